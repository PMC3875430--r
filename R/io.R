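# Readers and writers for the external formats the pipeline touches.
# Established parsers do the heavy lifting (Biostrings for FASTA/FASTQ,
# rtracklayer for GFF3/BED); this layer adds the package's conventions:
# U/T canonicalization, id uniqueness, count validation.

#' Read a FASTA file into a canonical DNA sequence set
#'
#' Wraps [Biostrings::readBStringSet] and enforces the package conventions:
#' sequences are upper-cased, U is canonicalized to T, the record id is the
#' first whitespace-delimited token of the header (the remainder is kept as
#' the `description` metadata column), ids must be unique and sequences
#' non-empty.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] named by record id, with a
#'   `description` metadata column. Record order is preserved.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stopf("FASTA parse error in %s: %s",
                                            path, conditionMessage(e)))
  headers <- names(set)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  widths <- Biostrings::width(set)
  if (any(widths == 0L)) {
    stopf("empty sequence for record '%s' (line %d) in %s",
          ids[which(widths == 0L)[1L]], fasta_header_line(path, which(widths == 0L)[1L]),
          path)
  }
  if (anyDuplicated(ids)) {
    d <- ids[duplicated(ids)][1L]
    stopf("duplicate record id '%s' (line %d) in %s",
          d, fasta_header_line(path, which(ids == d)[2L]), path)
  }
  seqs <- canonicalize_dna(set)
  if (any(grepl("[^ACGTN]", seqs))) {
    stopf("non-nucleotide characters in %s (record '%s')",
          path, ids[grep("[^ACGTN]", seqs)[1L]])
  }
  out <- Biostrings::DNAStringSet(seqs)
  names(out) <- ids
  S4Vectors::mcols(out)$description <- desc
  out
}

# Line number of the i-th header, for error messages.
fasta_header_line <- function(path, i) {
  grep("^>", readLines(path, warn = FALSE))[i]
}

#' Read a FASTQ file, dropping qualities
#'
#' Qualities are read but ignored downstream: quality/adapter filtering is
#' upstream of this pipeline's scope. U is canonicalized to T.
#'
#' @param path Path to a FASTQ file.
#' @return A [Biostrings::DNAStringSet] (names preserved, possibly
#'   non-unique as is usual for read files).
#' @export
read_fastq <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  set <- Biostrings::readBStringSet(path, format = "fastq")
  Biostrings::DNAStringSet(canonicalize_dna(set))
}

#' Read a collapsed-tag count table
#'
#' Dialect: TSV with a header line `sequence<TAB>lib1<TAB>lib2...`,
#' `#`-prefixed comment lines allowed. Missing cells are read as 0.
#'
#' @param path Path to the TSV file.
#' @return A data.frame with a `seq` column and one integer column per
#'   library. Zero rows for an empty (header-only) table.
#' @export
read_counts_table <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                          check.names = FALSE)
  if (ncol(df) < 2L) stopf("count table needs a sequence column and >=1 library")
  names(df)[1L] <- "seq"
  df$seq <- canonicalize_dna(df$seq)
  for (j in seq(2L, ncol(df))) {
    v <- df[[j]]
    v[is.na(v)] <- 0
    if (!is_count(v)) {
      stopf("column '%s' contains a negative or non-integer count", names(df)[j])
    }
    df[[j]] <- as.integer(v)
  }
  df
}

#' Write a collapsed-tag count table
#'
#' @param tags An `srna_tags` object (see [collapse_reads()]) or a data.frame
#'   with a `seq` column plus count columns.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts_table <- function(tags, path) {
  df <- if (inherits(tags, "srna_tags")) {
    data.frame(seq = tags$seq, tags$counts, check.names = FALSE)
  } else tags
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write intervals as GFF3
#'
#' Emits 1-based inclusive coordinates (the GFF3 convention) via
#' [rtracklayer::export]. Round-trips losslessly through [read_gff3()].
#'
#' @param gr A `GRanges` object; metadata columns are carried into the
#'   attribute column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gff3 <- function(gr, path) {
  stopifnot(methods::is(gr, "GRanges"))
  rtracklayer::export(gr, path, format = "gff3")
  invisible(path)
}

#' Read a GFF3 file
#'
#' @param path Path to a GFF3 file.
#' @return A `GRanges` object.
#' @export
read_gff3 <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  rtracklayer::import(path, format = "gff3")
}

#' Read a BED track
#'
#' BED input is 0-based half-open on disk; the returned `GRanges` follows the
#' internal 1-based closed convention (conversion is automatic).
#'
#' @param path Path to a BED file.
#' @return A `GRanges` object.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stopf("no such file: %s", path)
  rtracklayer::import(path, format = "bed")
}

#' Describe the sequencing libraries of a study
#'
#' A library spec records, per library, the developmental stage and flowering
#' group of the sampled plants and the clean-read total used as the
#' normalization denominator and as N1/N2 of the count test.
#'
#' @param name Library labels (e.g. `"CWR-V1"`).
#' @param stage `"vegetative"` or `"flowering"`, one per library.
#' @param group `"single-flowering"` or `"double-flowering"`, one per library.
#' @param total_clean_reads Positive integer clean-read totals (may be `NA`
#'   until realized totals are known).
#' @return A data.frame of class `library_spec`.
#' @export
library_spec <- function(name, stage, group, total_clean_reads = NA_integer_) {
  stage <- match.arg(stage, c("vegetative", "flowering"), several.ok = TRUE)
  group <- match.arg(group, c("single-flowering", "double-flowering"),
                     several.ok = TRUE)
  if (anyDuplicated(name)) stopf("library names must be unique")
  tot <- as.numeric(total_clean_reads)
  if (any(!is.na(tot) & tot <= 0)) {
    stopf("total_clean_reads must be > 0 for any library used in normalization")
  }
  df <- data.frame(name = name, stage = rep_len(stage, length(name)),
                   group = rep_len(group, length(name)),
                   total_clean_reads = rep_len(tot, length(name)),
                   stringsAsFactors = FALSE)
  class(df) <- c("library_spec", "data.frame")
  df
}

#' Read or write a library spec as YAML
#'
#' @param path YAML file with fields `name`, `stage`, `group`,
#'   `total_clean_reads` per library.
#' @return For `read_library_spec`, a `library_spec` data.frame.
#' @export
read_library_spec <- function(path) {
  y <- yaml::read_yaml(path)
  library_spec(vapply(y, `[[`, "", "name"),
               vapply(y, `[[`, "", "stage"),
               vapply(y, `[[`, "", "group"),
               vapply(y, function(e) as.numeric(e$total_clean_reads %||% NA),
                      0))
}

#' @rdname read_library_spec
#' @param libs A `library_spec` data.frame.
#' @export
write_library_spec <- function(libs, path) {
  yaml::write_yaml(lapply(seq_len(nrow(libs)), function(i) as.list(libs[i, ])),
                   path)
  invisible(path)
}
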