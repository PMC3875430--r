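# miRNA catalog: mature sequences, hairpin precursors, family map, star and
# precursor links, in the style of a miRBase mature.fa / hairpin.fa pair.

#' Build a miRNA catalog
#'
#' @param matures Named character vector or `DNAStringSet` of mature miRNA
#'   sequences (U or T accepted).
#' @param precursors Named character vector or `DNAStringSet` of hairpin
#'   precursor sequences.
#' @param family Named character vector mapping mature id to family name.
#'   When `NULL`, families are derived from the id by stripping arm suffixes
#'   (`-5p`/`-3p`), sub-mature indices (`.1`) and the trailing letter
#'   (`miR156a` -> `miR156`).
#' @param mature2prec Named list mapping mature id to the ids of the
#'   precursors containing it. When `NULL`, links are derived by exact
#'   substring search (a precursor may carry several matures; a multi-locus
#'   mature may link to several precursors).
#' @param star Named character vector mapping mature id to the id of its
#'   star (passenger-strand) partner; both must be catalog matures.
#' @param prec_loci Optional `GRanges` named by precursor id (genomic
#'   precursor locations).
#' @return An object of class `mirna_catalog`.
#' @export
mirna_catalog <- function(matures, precursors, family = NULL,
                          mature2prec = NULL, star = NULL, prec_loci = NULL) {
  mat <- stats::setNames(canonicalize_dna(matures), names(matures))
  pre <- stats::setNames(canonicalize_dna(precursors), names(precursors))
  if (is.null(names(mat)) || is.null(names(pre))) {
    stopf("matures and precursors must be named")
  }
  if (anyDuplicated(names(mat)) || anyDuplicated(names(pre))) {
    stopf("duplicate ids in catalog")
  }
  if (is.null(mature2prec)) {
    mature2prec <- lapply(mat, function(m) {
      names(pre)[vapply(pre, function(p) grepl(m, p, fixed = TRUE), TRUE)]
    })
  }
  orphan <- names(mat)[vapply(mature2prec[names(mat)], length, 0L) == 0L]
  if (length(orphan)) {
    stopf("mature(s) not found in any precursor: %s",
          paste(orphan, collapse = ", "))
  }
  for (id in names(mat)) {
    for (p in mature2prec[[id]]) {
      if (!grepl(mat[[id]], pre[[p]], fixed = TRUE)) {
        stopf("mature %s is not an exact substring of linked precursor %s",
              id, p)
      }
    }
  }
  if (is.null(family)) {
    family <- stats::setNames(derive_family(names(mat)), names(mat))
  }
  if (any(!nzchar(family)) || !all(names(mat) %in% names(family))) {
    stopf("every mature needs a non-empty family name")
  }
  if (!is.null(star)) {
    if (!all(star %in% names(mat)) || !all(names(star) %in% names(mat))) {
      stopf("star links must map catalog matures to catalog matures")
    }
  }
  structure(list(matures = mat, precursors = pre,
                 family = family[names(mat)],
                 mature2prec = mature2prec[names(mat)],
                 star = star, prec_loci = prec_loci),
            class = "mirna_catalog")
}

#' @export
print.mirna_catalog <- function(x, ...) {
  cat(sprintf(
    "mirna_catalog: %d matures, %d precursors, %d families, %d star links\n",
    length(x$matures), length(x$precursors),
    length(unique(x$family)), length(x$star %||% character(0))))
  invisible(x)
}

# miR156a-5p.2 -> miR156; oru-miR64 -> oru-miR64 family "oru-miR64".
derive_family <- function(id) {
  f <- sub("(-[35]p)?(\\.[0-9]+)?(\\*)?$", "", id)
  sub("([0-9])[a-z]+$", "\\1", f)
}

#' Read a catalog from miRBase-style FASTA files
#'
#' @param mature_fa,hairpin_fa FASTA paths with `>id` headers.
#' @param family_tsv Optional TSV (`mature_id<TAB>family`).
#' @param star_tsv Optional TSV (`mature_id<TAB>star_id`).
#' @return A `mirna_catalog`.
#' @export
read_mirna_catalog <- function(mature_fa, hairpin_fa, family_tsv = NULL,
                               star_tsv = NULL) {
  mat <- read_fasta(mature_fa)
  pre <- read_fasta(hairpin_fa)
  fam <- NULL
  if (!is.null(family_tsv)) {
    f <- utils::read.delim(family_tsv, header = TRUE, stringsAsFactors = FALSE)
    fam <- stats::setNames(f[[2L]], f[[1L]])
  }
  star <- NULL
  if (!is.null(star_tsv)) {
    s <- utils::read.delim(star_tsv, header = TRUE, stringsAsFactors = FALSE)
    star <- stats::setNames(s[[2L]], s[[1L]])
  }
  mirna_catalog(stats::setNames(as.character(mat), names(mat)),
                stats::setNames(as.character(pre), names(pre)),
                family = fam, star = star)
}

#' Enumerate templated +/-2-nt end variants of every catalog mature
#'
#' A variant is the mature trimmed or extended by at most `max_shift`
#' nucleotides at either end; extensions must match the precursor template
#' (templated isomiRs only -- non-templated tailing is never matched).
#' Offsets are signed: positive = extension, negative = trim, `(0, 0)` is
#' the annotated mature itself.
#'
#' @param catalog A `mirna_catalog`.
#' @param max_shift Maximum end shift in nt (default 2).
#' @param min_len,max_len Variant length bounds (the sequencing size range).
#' @return A data.frame (`seq`, `mature_id`, `off5`, `off3`), one row per
#'   distinct (variant sequence, mature) pair.
#' @export
variant_table <- function(catalog, max_shift = 2L,
                          min_len = 18L, max_len = 30L) {
  stopifnot(inherits(catalog, "mirna_catalog"))
  rows <- vector("list", length(catalog$matures))
  for (k in seq_along(catalog$matures)) {
    id <- names(catalog$matures)[k]
    m <- catalog$matures[[k]]
    got <- new.env(parent = emptyenv())
    for (p in catalog$mature2prec[[id]]) {
      prec <- catalog$precursors[[p]]
      # every occurrence of the mature in this precursor
      starts <- gregexpr(m, prec, fixed = TRUE)[[1L]]
      if (starts[1L] == -1L) next
      for (s in starts) {
        e <- s + nchar(m) - 1L
        for (d5 in -max_shift:max_shift) for (d3 in -max_shift:max_shift) {
          vs <- s - d5; ve <- e + d3
          if (vs < 1L || ve > nchar(prec) || ve - vs + 1L < min_len ||
              ve - vs + 1L > max_len) next
          v <- substr(prec, vs, ve)
          key <- paste(v, d5, d3)
          if (is.null(got[[key]])) got[[key]] <- c(v, d5, d3)
        }
      }
    }
    vals <- as.list(got)
    if (length(vals)) {
      mm <- do.call(rbind, vals)
      rows[[k]] <- data.frame(seq = mm[, 1L], mature_id = id,
                              off5 = as.integer(mm[, 2L]),
                              off3 = as.integer(mm[, 3L]),
                              stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}
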