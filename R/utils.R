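# Internal helpers shared across modules.

# Canonical internal alphabet is DNA: U is converted to T on input and all
# sequence comparisons happen in DNA space. RNA views (folding, primer
# reporting) translate on the fly.
canonicalize_dna <- function(x) {
  x <- toupper(as.character(x))
  chartr("U", "T", x)
}

as_rna <- function(x) chartr("T", "U", toupper(as.character(x)))

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && all(is.finite(x)) && all(x >= 0) && all(x == floor(x))
}

#' Construct a genomic interval
#'
#' Thin constructor around [GenomicRanges::GRanges] used throughout the
#' package. Internally all coordinates follow the Bioconductor convention
#' (1-based, closed); `zero_based = TRUE` accepts 0-based half-open input
#' (the BED convention) and converts it.
#'
#' @param chrom Reference sequence name.
#' @param start,end Interval coordinates. With `zero_based = FALSE` (default)
#'   these are 1-based inclusive; with `zero_based = TRUE` they are 0-based
#'   half-open.
#' @param strand `"+"` or `"-"` (mandatory; `"*"` is rejected).
#' @param zero_based Interpret `start`/`end` as 0-based half-open.
#' @param seqlengths Optional named vector of chromosome lengths used to
#'   validate bounds.
#' @return A `GRanges` object.
#' @examples
#' genomic_interval("chr1", 0, 10, "+", zero_based = TRUE)  # GFF3 start=1 end=10
#' @export
genomic_interval <- function(chrom, start, end, strand,
                             zero_based = FALSE, seqlengths = NULL) {
  if (zero_based) {
    if (any(start >= end)) stopf("need start < end in 0-based half-open input")
    start <- start + 1L
  }
  if (any(start > end)) stopf("need start <= end (1-based closed)")
  if (any(!strand %in% c("+", "-"))) {
    stopf("strand must be '+' or '-' for every interval")
  }
  gr <- GenomicRanges::GRanges(chrom, IRanges::IRanges(start, end), strand)
  if (!is.null(seqlengths)) {
    bad <- GenomicRanges::end(gr) >
      seqlengths[as.character(GenomicRanges::seqnames(gr))]
    if (any(bad)) stopf("interval exceeds chromosome length")
  }
  gr
}
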