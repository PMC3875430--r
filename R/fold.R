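# Pluggable RNA secondary-structure folding.
#
# Two engines satisfy the same contract (dot-bracket + energy, deterministic
# for a fixed engine/version):
#   * "builtin" -- the package's maximum weighted base-pairing folder with a
#     stacking-energy readout (compiled; no external dependency);
#   * "vienna"  -- RNAfold from the ViennaRNA suite, when installed.
# Acceptance thresholds downstream are calibrated per engine; the shipped
# defaults refer to the builtin engine.

#' Fold an RNA/DNA sequence into a secondary structure
#'
#' @param seq Sequence (U or T accepted), length >= 2; folding windows
#'   shorter than ~40 nt are of little use for hairpin calling.
#' @param engine `"builtin"` (default) or `"vienna"` (requires the
#'   `RNAfold` executable on the PATH).
#' @param min_loop Minimum hairpin loop size for the builtin engine.
#' @return A list of class `rna_fold`: `structure` (dot-bracket string,
#'   same length as `seq`), `mfe` (kcal/mol, <= 0), `partner` (1-based
#'   pairing vector, 0 = unpaired), `engine`.
#' @examples
#' f <- fold_rna(paste0(strrep("A", 60)))   # no pairs, mfe = 0
#' f$mfe
#' @export
fold_rna <- function(seq, engine = c("builtin", "vienna"), min_loop = 3L) {
  engine <- match.arg(engine)
  s <- canonicalize_dna(seq)
  if (nchar(s) < 2L) stopf("sequence too short to fold")
  if (engine == "builtin") {
    res <- nussinov_fold(s, min_loop = as.integer(min_loop))
    res$engine <- "builtin/1"
  } else {
    res <- rnafold_engine(s)
    res$engine <- "vienna/RNAfold"
  }
  stopifnot(nchar(res$structure) == nchar(s))
  class(res) <- "rna_fold"
  res
}

rnafold_engine <- function(seq) {
  exe <- Sys.which("RNAfold")
  if (!nzchar(exe)) {
    stopf(paste("folding engine 'vienna' unavailable: RNAfold not found on",
                "the PATH; install ViennaRNA or use engine = 'builtin'"))
  }
  out <- system2(exe, c("--noPS"), input = as_rna(seq), stdout = TRUE)
  line <- out[length(out)]
  db <- sub("\\s.*$", "", line)
  mfe <- as.numeric(sub("^.*\\(\\s*(-?[0-9.]+)\\)\\s*$", "\\1", line))
  list(structure = db, mfe = mfe, partner = dotbracket_partner(db))
}

#' @export
print.rna_fold <- function(x, ...) {
  cat(sprintf("rna_fold [%s]: %d nt, %d pairs, mfe %.2f kcal/mol\n",
              x$engine, nchar(x$structure), sum(x$partner > seq_along(x$partner)),
              x$mfe))
  invisible(x)
}

#' Pairing partners of a dot-bracket string
#'
#' @param db Dot-bracket string (only `(`, `)`, `.`).
#' @return Integer vector; `partner[i]` is the 1-based partner of position
#'   `i`, 0 when unpaired.
#' @export
dotbracket_partner <- function(db) {
  ch <- strsplit(db, "")[[1L]]
  partner <- integer(length(ch))
  stack <- integer(0)
  for (i in seq_along(ch)) {
    if (ch[i] == "(") {
      stack <- c(stack, i)
    } else if (ch[i] == ")") {
      if (!length(stack)) stopf("unbalanced dot-bracket string")
      j <- stack[length(stack)]
      stack <- stack[-length(stack)]
      partner[i] <- j; partner[j] <- i
    }
  }
  if (length(stack)) stopf("unbalanced dot-bracket string")
  partner
}
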