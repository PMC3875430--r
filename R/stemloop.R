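# Stem-loop RT-qPCR assay design for mature miRNAs.
#
# The looped RT primer carries a fixed scaffold whose 3' terminal 8 nt are
# reverse-complementary to the miRNA's 3' octamer; the forward PCR primer
# reproduces the miRNA's first 10 nt (with an optional 5' clamp); the
# reverse PCR primer is a universal primer annealing within the scaffold.
# The amplicon therefore grows linearly with miRNA length:
# amplicon = miRNA length + scaffold constant (48 nt by default, calibrated
# so a 21-nt miRNA yields a 69-bp product).

# Fixed RT scaffold (44 nt stem-loop); its 3' end is completed per-miRNA.
STEMLOOP_SCAFFOLD <- "GTCGTATCCAGTGCAGGGTCCGAGGTATTCGCACTGGATACGAC"
UNIVERSAL_REVERSE <- "GTGCAGGGTCCGAGGT"

#' Design a stem-loop RT-qPCR assay for one miRNA
#'
#' @param mirna Mature miRNA sequence, 18-30 nt (U or T accepted).
#' @param scaffold_constant Number of non-miRNA nucleotides contributed to
#'   the amplicon by the RT scaffold and primer layout (default 48).
#' @param forward_clamp Optional 5' extension prepended to the forward
#'   primer to raise its melting temperature.
#' @return An object of class `stemloop_assay`: `rt_primer`,
#'   `forward_primer`, `universal_reverse`, `amplicon_length`, `mirna`.
#'   The RT primer's 3' octamer reverse-complements the miRNA's 3' octamer
#'   exactly; the forward primer ends with the miRNA's first 10 nt.
#' @examples
#' a <- design_stemloop_assay("UGACAGAAGAGAGUGAGCACA")  # 21 nt
#' a$amplicon_length  # 69
#' @export
design_stemloop_assay <- function(mirna, scaffold_constant = 48L,
                                  forward_clamp = "GCG") {
  m <- canonicalize_dna(mirna)
  n <- nchar(m)
  if (n < 10L) stopf("miRNA shorter than 10 nt cannot anchor the primers")
  if (n < 18L || n > 30L) stopf("miRNA length %d outside the 18-30 nt range", n)
  tail8 <- substr(m, n - 7L, n)
  rt <- paste0(STEMLOOP_SCAFFOLD, revcomp(tail8))
  fwd <- paste0(forward_clamp, substr(m, 1L, 10L))
  structure(list(mirna = as_rna(m),
                 rt_primer = rt,
                 forward_primer = fwd,
                 universal_reverse = UNIVERSAL_REVERSE,
                 amplicon_length = n + as.integer(scaffold_constant)),
            class = "stemloop_assay")
}

#' @export
print.stemloop_assay <- function(x, ...) {
  cat("stem-loop RT-qPCR assay\n")
  cat("  miRNA:            ", x$mirna, sprintf(" (%d nt)\n", nchar(x$mirna)))
  cat("  RT primer:        ", x$rt_primer, "\n")
  cat("  forward primer:   ", x$forward_primer, "\n")
  cat("  universal reverse:", x$universal_reverse, "\n")
  cat("  amplicon length:  ", x$amplicon_length, "bp\n")
  invisible(x)
}
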