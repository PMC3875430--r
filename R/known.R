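# Known-miRNA quantification: +/-2-nt templated variant matching, family
# rollup, star dominance, first-base composition and stage/group occupancy.

#' Match tags to known miRNAs with templated end variants
#'
#' A tag is assigned to a mature if it equals the mature or one of its
#' templated +/-2-nt end variants (see [variant_table()]). A tag claimed by
#' several matures is assigned to exactly one -- the mature with a zero
#' offset if any, else the lowest total `|off5| + |off3|`, else the
#' lexicographically smallest id -- so counts are never duplicated.
#'
#' @param tags An `srna_tags` object (ideally after [match_genome()]).
#' @param catalog A [mirna_catalog()].
#' @param max_shift Maximum end shift (default 2 nt).
#' @return A data.frame with one row per matched tag per library:
#'   `mirna_id`, `library`, `count`, `off5`, `off3`, `seq`. Zero-count
#'   rows are dropped.
#' @export
match_known <- function(tags, catalog, max_shift = 2L) {
  stopifnot(inherits(tags, "srna_tags"))
  vt <- variant_table(catalog, max_shift = max_shift)
  hit <- vt[vt$seq %in% tags$seq, , drop = FALSE]
  if (nrow(hit) == 0L) {
    return(data.frame(mirna_id = character(0), library = character(0),
                      count = integer(0), off5 = integer(0),
                      off3 = integer(0), seq = character(0)))
  }
  # tie-break: zero offset, then minimal total offset, then smallest id
  pri <- (hit$off5 != 0L | hit$off3 != 0L) * 1000L +
    (abs(hit$off5) + abs(hit$off3)) * 10L
  ord <- order(hit$seq, pri, hit$mature_id)
  hit <- hit[ord, , drop = FALSE]
  hit <- hit[!duplicated(hit$seq), , drop = FALSE]

  ti <- match(hit$seq, tags$seq)
  libs <- colnames(tags$counts)
  out <- do.call(rbind, lapply(seq_along(libs), function(j) {
    data.frame(mirna_id = hit$mature_id, library = libs[j],
               count = tags$counts[ti, j], off5 = hit$off5, off3 = hit$off3,
               seq = hit$seq, stringsAsFactors = FALSE)
  }))
  out <- out[out$count > 0L, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate matched records to a mature x library count matrix
#'
#' `raw_count` per (mature, library) is the sum over its variant records.
#'
#' @param records Output of [match_known()].
#' @param catalog A `mirna_catalog`; fixes row order and includes
#'   zero-count matures.
#' @return Integer matrix, matures x libraries.
#' @export
expression_matrix <- function(records, catalog) {
  ids <- names(catalog$matures)
  libs <- unique(records$library)
  m <- matrix(0L, nrow = length(ids), ncol = length(libs),
              dimnames = list(ids, libs))
  if (nrow(records)) {
    agg <- rowsum(records$count,
                  paste(records$mirna_id, records$library, sep = "\r"))
    key <- do.call(rbind, strsplit(rownames(agg), "\r", fixed = TRUE))
    m[cbind(match(key[, 1L], ids), match(key[, 2L], libs))] <- agg[, 1L]
  }
  m
}

#' Roll member counts up to miRNA families
#'
#' @param expr A mature x library count matrix ([expression_matrix()]).
#' @param catalog A `mirna_catalog` supplying the family map.
#' @return Family x library matrix; totals conserve member sums.
#' @export
family_rollup <- function(expr, catalog) {
  fam <- catalog$family[rownames(expr)]
  if (any(is.na(fam) | !nzchar(fam))) {
    stopf("member with no family: %s",
          paste(rownames(expr)[is.na(fam) | !nzchar(fam)], collapse = ", "))
  }
  rowsum(expr, fam)
}

#' Detect star-strand dominance within one library
#'
#' For every mature with a star link, compares raw counts in one library;
#' the star dominates when its count strictly exceeds the mature's (ties go
#' to the mature).
#'
#' @param expr A mature x library count matrix.
#' @param catalog A `mirna_catalog` with `star` links.
#' @param library Library name (column of `expr`).
#' @return data.frame (`mirna_id`, `star_id`, `mirna_count`, `star_count`,
#'   `dominant`).
#' @export
detect_star_dominance <- function(expr, catalog, library) {
  if (is.null(catalog$star) || length(catalog$star) == 0L) {
    return(data.frame(mirna_id = character(0), star_id = character(0),
                      mirna_count = integer(0), star_count = integer(0),
                      dominant = character(0)))
  }
  if (!library %in% colnames(expr)) stopf("unknown library '%s'", library)
  mid <- names(catalog$star); sid <- unname(catalog$star)
  mc <- expr[mid, library]; sc <- expr[sid, library]
  data.frame(mirna_id = mid, star_id = sid,
             mirna_count = unname(mc), star_count = unname(sc),
             dominant = ifelse(sc > mc, "star", "mature"),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' 5'-terminal base composition
#'
#' @param seqs Character vector of sequences (U or T accepted).
#' @return Named fractions over A, C, G, U summing to 1.
#' @export
first_base_composition <- function(seqs) {
  if (length(seqs) == 0L) stopf("empty sequence set")
  b <- substr(as_rna(seqs), 1L, 1L)
  tab <- table(factor(b, levels = c("A", "C", "G", "U")))
  as.numeric(tab) / length(seqs) -> fr
  stats::setNames(fr, c("A", "C", "G", "U"))
}

#' Partition expressed miRNAs by developmental stage and flowering group
#'
#' "Expressed" means raw count >= `threshold` (default 1; the classical
#' presence call) in at least one library of the set. The stage classes
#' (vegetative-only / flowering-only / both) and the group classes
#' (single-flowering-only / double-flowering-only / both) each partition the
#' expressed universe, so sizes sum to the universe size.
#'
#' @param expr A mature x library count matrix.
#' @param libs A [library_spec()] covering the columns of `expr`.
#' @param threshold Minimum raw count to call a miRNA expressed.
#' @return List with `universe` (expressed ids), `stage` and `group`
#'   (each a list of id vectors), and `sizes` (named integer vector).
#' @export
partition_by_stage_group <- function(expr, libs, threshold = 1L) {
  if (!all(colnames(expr) %in% libs$name)) {
    stopf("library spec does not cover all expression columns")
  }
  spec <- libs[match(colnames(expr), libs$name), ]
  inlib <- expr >= threshold
  expressed <- rownames(expr)[rowSums(inlib) > 0L]
  in_set <- function(sel) rowSums(inlib[expressed, sel, drop = FALSE]) > 0L
  veg <- in_set(spec$stage == "vegetative")
  flo <- in_set(spec$stage == "flowering")
  sgl <- in_set(spec$group == "single-flowering")
  dbl <- in_set(spec$group == "double-flowering")
  stage <- list(vegetative_only = expressed[veg & !flo],
                flowering_only = expressed[!veg & flo],
                both_stages = expressed[veg & flo])
  group <- list(single_only = expressed[sgl & !dbl],
                double_only = expressed[!sgl & dbl],
                both_groups = expressed[sgl & dbl])
  sizes <- c(universe = length(expressed),
             vapply(stage, length, 0L), vapply(group, length, 0L))
  list(universe = expressed, stage = stage, group = group, sizes = sizes)
}
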