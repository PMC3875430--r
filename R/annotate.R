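# Annotation cascade: collapse reads to unique tags, match tags perfectly to
# the genome on both strands, assign each tag exactly one category by a fixed
# priority, and summarize per-category read/unique counts.

CATEGORY_LEVELS <- c("rRNA", "tRNA", "snRNA", "snoRNA", "scRNA", "repeat",
                     "exon_sense", "exon_antisense",
                     "intron_sense", "intron_antisense",
                     "known_miRNA", "unannotated")

DEFAULT_PRIORITY <- c("rRNA", "tRNA", "snRNA", "snoRNA", "scRNA", "repeat",
                      "exon", "intron", "known_miRNA")

#' Collapse reads to unique tags with per-library counts
#'
#' Reads are length-filtered to the small-RNA window (18-30 nt by default,
#' matching the gel-purified size range) and collapsed to distinct sequences.
#' Per-library counts are conserved: the sum of tag counts equals the number
#' of retained input reads in every library.
#'
#' @param reads_by_lib Named list, one element per library, each a
#'   `DNAStringSet` or character vector of read sequences.
#' @param min_len,max_len Retained length range, inclusive.
#' @return An object of class `srna_tags`: a list with `seq` (character
#'   vector of unique tag sequences), `counts` (integer matrix, tags x
#'   libraries), and `n_dropped` (reads outside the length window, per
#'   library). After [match_genome()] it gains `loci` and `genome_matched`.
#' @export
collapse_reads <- function(reads_by_lib, min_len = 18L, max_len = 30L) {
  if (is.null(names(reads_by_lib)) || any(names(reads_by_lib) == "")) {
    stopf("reads_by_lib must be a named list (one element per library)")
  }
  libs <- names(reads_by_lib)
  kept <- lapply(reads_by_lib, function(r) {
    r <- canonicalize_dna(r)
    r[nchar(r) >= min_len & nchar(r) <= max_len]
  })
  n_dropped <- vapply(seq_along(libs), function(i) {
    length(reads_by_lib[[i]]) - length(kept[[i]])
  }, 0L)
  names(n_dropped) <- libs
  all_seq <- sort(unique(unlist(kept, use.names = FALSE)))
  counts <- matrix(0L, nrow = length(all_seq), ncol = length(libs),
                   dimnames = list(NULL, libs))
  for (i in seq_along(libs)) {
    tb <- table(kept[[i]])
    counts[match(names(tb), all_seq), i] <- as.integer(tb)
  }
  structure(list(seq = all_seq, counts = counts, n_dropped = n_dropped,
                 hits = NULL, n_loci = NULL, genome_matched = NULL),
            class = "srna_tags")
}

#' @export
print.srna_tags <- function(x, ...) {
  cat(sprintf("srna_tags: %d unique tags, %d libraries (%s)\n",
              length(x$seq), ncol(x$counts),
              paste(colnames(x$counts), collapse = ", ")))
  if (!is.null(x$genome_matched)) {
    cat(sprintf("  genome-matched: %d of %d tags\n",
                sum(x$genome_matched), length(x$seq)))
  }
  invisible(x)
}

#' @export
length.srna_tags <- function(x) length(x$seq)

#' Find every perfect full-length genomic match of each tag
#'
#' Exact matching only (0 mismatches), on both strands, mirroring an
#' alignment run with mismatches disabled. Tags with zero loci are flagged
#' genome-unmatched; downstream stages operate on the matched ("clean")
#' subset only.
#'
#' @param tags An `srna_tags` object.
#' @param genome A named `DNAStringSet` (the reference chromosomes).
#' @return `tags` with `hits` (data.frame of perfect matches: `tag` index,
#'   `chrom`, `start`, `end`, `strand`), `n_loci` (loci per tag) and
#'   `genome_matched` (logical) filled in.
#' @export
match_genome <- function(tags, genome) {
  stopifnot(inherits(tags, "srna_tags"))
  if (is.null(names(genome))) stopf("genome must be a named DNAStringSet")
  n <- length(tags$seq)
  acc <- list()
  widths <- nchar(tags$seq)
  for (w in sort(unique(widths))) {
    idx <- which(widths == w)
    pd <- Biostrings::PDict(tags$seq[idx])
    for (chr in names(genome)) {
      subj <- genome[[chr]]
      clen <- length(subj)
      m <- Biostrings::matchPDict(pd, subj)
      cnt <- S4Vectors::elementNROWS(m)
      if (sum(cnt) > 0) {
        st <- BiocGenerics::unlist(BiocGenerics::start(m))
        acc[[length(acc) + 1L]] <- data.frame(
          tag = rep(idx, cnt), chrom = chr, start = st, end = st + w - 1L,
          strand = "+", stringsAsFactors = FALSE)
      }
      mr <- Biostrings::matchPDict(pd, Biostrings::reverseComplement(subj))
      cntr <- S4Vectors::elementNROWS(mr)
      if (sum(cntr) > 0) {
        str <- BiocGenerics::unlist(BiocGenerics::start(mr))
        # position in revcomp space -> forward coordinates
        fs <- clen - (str + w - 1L) + 1L
        acc[[length(acc) + 1L]] <- data.frame(
          tag = rep(idx, cntr), chrom = chr, start = fs, end = fs + w - 1L,
          strand = "-", stringsAsFactors = FALSE)
      }
    }
  }
  hits <- if (length(acc)) do.call(rbind, acc) else
    data.frame(tag = integer(0), chrom = character(0), start = integer(0),
               end = integer(0), strand = character(0))
  hits <- hits[order(hits$tag, hits$chrom, hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  tags$hits <- hits
  tags$n_loci <- tabulate(hits$tag, nbins = n)
  tags$genome_matched <- tags$n_loci > 0L
  tags
}

# GRanges view of all (or a subset of) perfect-match loci.
hits_granges <- function(tags, rows = seq_len(nrow(tags$hits))) {
  h <- tags$hits[rows, , drop = FALSE]
  GenomicRanges::GRanges(h$chrom, IRanges::IRanges(h$start, h$end), h$strand)
}

#' Loci of one tag as a `GRanges`
#'
#' @param tags An `srna_tags` object after [match_genome()].
#' @param i Tag index (into `tags$seq`).
#' @return A `GRanges` of the tag's perfect-match loci.
#' @export
tag_loci <- function(tags, i) {
  hits_granges(tags, which(tags$hits$tag == i))
}

#' Assign each genome-matched tag exactly one category
#'
#' The cascade mirrors the classical small-RNA filtering order: structural
#' RNA classes first (rRNA, tRNA, snRNA, snoRNA, scRNA), then repeats, then
#' exon/intron, then known miRNAs (by sequence identity to the catalog,
#' including templated +/-2-nt end variants), and finally `unannotated`.
#' A multi-locus tag is annotated by the highest-priority class any of its
#' loci overlaps; its reads are counted once, never per locus.
#'
#' Sense/antisense for exon and intron is decided by strand agreement between
#' the tag locus and the overlapping feature; when both sense and antisense
#' overlaps exist, sense wins.
#'
#' @param tags An `srna_tags` object after [match_genome()].
#' @param tracks Named list of `GRanges` interval sets. Recognized names:
#'   `rRNA`, `tRNA`, `snRNA`, `snoRNA`, `scRNA`, `repeat`, `exon`, `intron`
#'   (any subset; `exon`/`intron` must carry feature strand).
#' @param catalog Optional [mirna_catalog()]; when supplied, tags equal to a
#'   catalog mature or one of its templated +/-2-nt variants are classed
#'   `known_miRNA` (unless a higher-priority track claims them first).
#' @param priority Character vector giving the cascade order over track names
#'   plus `"known_miRNA"`. Unknown names are a configuration error.
#' @return A data.frame (`seq`, `category`, `evidence`) with one row per
#'   genome-matched tag, plus the tag count columns. `category` is a factor
#'   over the Table-style category levels.
#' @export
assign_categories <- function(tags, tracks, catalog = NULL,
                              priority = DEFAULT_PRIORITY) {
  stopifnot(inherits(tags, "srna_tags"))
  if (is.null(tags$hits)) stopf("run match_genome() before assign_categories()")
  if (length(bad <- setdiff(priority, c(DEFAULT_PRIORITY, names(tracks))))) {
    stopf("unknown track name in priority: %s", paste(bad, collapse = ", "))
  }
  loci <- hits_granges(tags)
  tag_of_locus <- tags$hits$tag
  locus_strand <- tags$hits$strand

  category <- rep(NA_character_, length(tags$seq))
  evidence <- rep(NA_character_, length(tags$seq))

  variant_ids <- if (!is.null(catalog)) variant_table(catalog)$seq
                 else character(0)

  for (cls in priority) {
    if (cls == "known_miRNA") {
      unset <- which(is.na(category) & tags$genome_matched)
      hit <- unset[tags$seq[unset] %in% variant_ids]
      category[hit] <- "known_miRNA"
      evidence[hit] <- "catalog-sequence-match"
      next
    }
    trk <- tracks[[cls]]
    if (is.null(trk) || length(trk) == 0L) next
    use_strand <- cls %in% c("exon", "intron")
    ov <- GenomicRanges::findOverlaps(loci, trk, ignore.strand = TRUE)
    if (length(ov) == 0L) next
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    t_idx <- tag_of_locus[qh]
    ok <- is.na(category[t_idx])
    qh <- qh[ok]; sh <- sh[ok]; t_idx <- t_idx[ok]
    if (length(qh) == 0L) next
    if (use_strand) {
      same <- locus_strand[qh] == as.character(GenomicRanges::strand(trk))[sh]
      # sense wins over antisense: order each tag's pairs sense-first
      ord <- order(t_idx, !same)
      first <- ord[!duplicated(t_idx[ord])]
      tg <- t_idx[first]
      category[tg] <- paste0(cls,
                             ifelse(same[first], "_sense", "_antisense"))
      evidence[tg] <- sprintf("%s:%s", cls, as.character(trk)[sh[first]])
    } else {
      first <- !duplicated(t_idx)
      category[t_idx[first]] <- cls
      evidence[t_idx[first]] <-
        sprintf("%s:%s", cls, as.character(trk)[sh[first]])
    }
  }
  category[is.na(category) & tags$genome_matched] <- "unannotated"
  out <- data.frame(seq = tags$seq, category = factor(category, CATEGORY_LEVELS),
                    evidence = evidence, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(tags$counts))[tags$genome_matched, , drop = FALSE]
}

#' Summarize category composition per library
#'
#' @param annot Annotation records from [assign_categories()].
#' @param totals Named numeric vector of clean-read totals per library
#'   (defaults to the column sums of the records, which equal the clean
#'   totals when every clean tag has a record).
#' @return A data.frame with one row per category: unique-tag counts, read
#'   counts and read percentages per library. Read counts partition the
#'   clean total exactly.
#' @export
summarize_categories <- function(annot, totals = NULL) {
  libs <- setdiff(names(annot), c("seq", "category", "evidence"))
  reads <- rowsum_all_levels(as.matrix(annot[libs]), annot$category,
                             CATEGORY_LEVELS)
  uniq <- rowsum_all_levels((as.matrix(annot[libs]) > 0) + 0L, annot$category,
                            CATEGORY_LEVELS)
  if (is.null(totals)) totals <- colSums(reads)
  pct <- category_percentages(reads, totals[libs])
  out <- data.frame(category = CATEGORY_LEVELS, stringsAsFactors = FALSE)
  for (l in libs) {
    out[[paste0(l, "_unique")]] <- uniq[, l]
    out[[paste0(l, "_reads")]] <- reads[, l]
    out[[paste0(l, "_pct")]] <- pct[, l]
  }
  rownames(out) <- NULL
  out
}

#' Read percentages of the clean totals
#'
#' The elementary reporting arithmetic behind the category table:
#' `reads / total * 100` per library, conventionally printed to one decimal.
#'
#' @param reads Numeric matrix (category x library) of read counts.
#' @param totals Clean-read total per library (recycled if scalar).
#' @return Matrix of percentages with the shape of `reads`.
#' @export
category_percentages <- function(reads, totals) {
  reads <- as.matrix(reads)
  if (any(totals <= 0)) stopf("clean totals must be positive")
  sweep(reads, 2L, totals, "/") * 100
}

#' Per-length read fractions
#'
#' @param tags An `srna_tags` object.
#' @param lengths Length range to report (rows of the result).
#' @return Matrix (length x library) of read fractions; columns sum to 1.
#' @export
length_distribution <- function(tags, lengths = 18:30) {
  stopifnot(inherits(tags, "srna_tags"))
  len <- nchar(tags$seq)
  agg <- rowsum_all_levels(tags$counts, factor(len, levels = lengths),
                           as.character(lengths))
  sweep(agg, 2L, colSums(agg), "/")
}

# rowsum() drops empty groups; this keeps every level as a (zero) row.
rowsum_all_levels <- function(x, group, levels) {
  part <- rowsum(x, as.character(group))
  full <- matrix(0, nrow = length(levels), ncol = ncol(x),
                 dimnames = list(levels, colnames(x)))
  full[rownames(part), ] <- part
  full
}
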