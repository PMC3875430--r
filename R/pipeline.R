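# Pipeline orchestration: compose the stages in the canonical order and
# emit the report tables; partition-identity checks for summary marginals.

#' Run the small-RNA analysis pipeline
#'
#' Stages, in order: collapse reads to tags, perfect genome matching,
#' category assignment, category/length summaries, known-miRNA
#' quantification (variants, families, occupancy partitions, star
#' dominance), novel-miRNA discovery on unannotated tags, and pairwise
#' differential expression with F/E/N phase classification over known and
#' novel matures. Deterministic given its inputs; every report carries the
#' thresholds used.
#'
#' @param reads Named list of read vectors (or `DNAStringSet`s), one per
#'   library.
#' @param genome Named `DNAStringSet`.
#' @param tracks Named list of annotation `GRanges` (see
#'   [assign_categories()]; an optional `utr` track improves novel-miRNA
#'   context calls).
#' @param catalog A [mirna_catalog()].
#' @param libspec A [library_spec()]; clean totals are filled in from the
#'   genome-matched read counts.
#' @param hairpin Thresholds from [hairpin_config()].
#' @param de Thresholds from [de_config()].
#' @param run_novel Toggle the novel-discovery stage.
#' @param outdir Optional directory: report tables are additionally written
#'   as TSV.
#' @return List of class `srna_pipeline`: `tags`, `annot`,
#'   `category_summary`, `length_dist`, `known` (records, expression,
#'   families, partition, star dominance), `novel`, `de`, `phase`,
#'   `libspec`, `settings`.
#' @export
run_srna_pipeline <- function(reads, genome, tracks, catalog, libspec,
                              hairpin = hairpin_config(), de = de_config(),
                              run_novel = TRUE, outdir = NULL) {
  tags <- collapse_reads(reads)
  tags <- match_genome(tags, genome)
  clean_tot <- colSums(tags$counts[tags$genome_matched, , drop = FALSE])
  libspec$total_clean_reads <- as.numeric(clean_tot[libspec$name])

  annot <- assign_categories(tags, tracks, catalog)
  summary <- summarize_categories(annot, clean_tot)
  lens <- length_distribution(tags)

  records <- match_known(tags, catalog)
  expr <- expression_matrix(records, catalog)
  fams <- family_rollup(expr, catalog)
  partition <- partition_by_stage_group(expr, libspec)
  star <- do.call(rbind, lapply(libspec$name, function(l) {
    d <- detect_star_dominance(expr, catalog, l)
    if (nrow(d)) d$library <- l
    d
  }))

  novel <- NULL
  novel_expr <- NULL
  if (run_novel) {
    novel <- discover_novel(tags, annot, genome, tracks, config = hairpin)
    if (nrow(novel$novel)) {
      idx <- match(novel$novel$seq, tags$seq)
      novel_expr <- tags$counts[idx, , drop = FALSE]
      rownames(novel_expr) <- novel$novel$id
    }
  }

  counts_all <- rbind(expr, novel_expr)
  keep <- low_count_filter(counts_all)
  detab <- de_table(counts_all[keep, , drop = FALSE], libspec, config = de)
  phase <- phase_classification(detab, libspec)

  res <- structure(list(tags = tags, annot = annot,
                        category_summary = summary, length_dist = lens,
                        known = list(records = records, expression = expr,
                                     families = fams, partition = partition,
                                     star_dominance = star),
                        novel = novel, de = detab, phase = phase,
                        libspec = libspec,
                        settings = list(hairpin = hairpin, de = de)),
                   class = "srna_pipeline")
  if (!is.null(outdir)) write_pipeline_reports(res, outdir)
  res
}

#' @export
print.srna_pipeline <- function(x, ...) {
  cat("srna_pipeline result\n")
  cat(sprintf("  libraries:    %s\n", paste(x$libspec$name, collapse = ", ")))
  cat(sprintf("  clean tags:   %d (of %d unique)\n",
              sum(x$tags$genome_matched), length(x$tags$seq)))
  cat(sprintf("  known miRNAs: %d expressed\n",
              sum(rowSums(x$known$expression) > 0)))
  if (!is.null(x$novel)) {
    cat(sprintf("  novel miRNAs: %d accepted\n", nrow(x$novel$novel)))
  }
  cat(sprintf("  DE tests:     %d; phase classes: %s\n", nrow(x$de),
              paste(names(table(x$phase$phase)), table(x$phase$phase),
                    sep = "=", collapse = " ")))
  invisible(x)
}

write_pipeline_reports <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  wt <- function(df, file) {
    path <- file.path(outdir, file)
    hdr <- sprintf("# mirphase report | de: floor=%g fc>%g | hairpin: mfe<=%g mm<=%d",
                   res$settings$de$floor, res$settings$de$fc_threshold,
                   res$settings$hairpin$mfe_max, res$settings$hairpin$max_mismatch)
    writeLines(hdr, path)
    suppressWarnings(utils::write.table(df, path, sep = "\t", quote = FALSE,
                                        row.names = FALSE, append = TRUE))
  }
  wt(res$category_summary, "category_summary.tsv")
  wt(data.frame(length = rownames(res$length_dist), res$length_dist,
                check.names = FALSE), "length_distribution.tsv")
  wt(data.frame(mirna_id = rownames(res$known$expression),
                res$known$expression, check.names = FALSE),
     "known_expression.tsv")
  wt(data.frame(family = rownames(res$known$families), res$known$families,
                check.names = FALSE), "families.tsv")
  if (!is.null(res$novel)) wt(res$novel$candidates, "novel_candidates.tsv")
  if (!is.null(res$novel) && nrow(res$novel$novel)) {
    wt(res$novel$novel, "novel_mirnas.tsv")
  }
  wt(res$de, "differential_expression.tsv")
  wt(res$phase, "phase_classification.tsv")
  invisible(outdir)
}

#' Check partition identities over reported marginals
#'
#' Verifies that printed summary marginals are internally consistent:
#' exclusive parts plus the shared remainder reconstruct the stated
#' universe. Each check is a list with `name`, `total`, `parts` (numeric
#' vector) and optionally `remainder` (the value the report prints for
#' `total - sum(parts)`; when omitted only non-negativity is checked).
#'
#' @param checks List of checks as described.
#' @return data.frame: `name`, `total`, `parts_sum`, `implied`,
#'   `stated`, `pass`.
#' @examples
#' consistency_report(list(
#'   list(name = "stages", total = 512, parts = c(39, 42), remainder = 431)))
#' @export
consistency_report <- function(checks) {
  rows <- lapply(checks, function(ck) {
    implied <- ck$total - sum(ck$parts)
    stated <- ck$remainder %||% NA_real_
    pass <- implied >= 0 && (is.na(stated) || implied == stated)
    data.frame(name = ck$name, total = ck$total, parts_sum = sum(ck$parts),
               implied = implied, stated = stated, pass = pass,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Recovery of planted truth by a pipeline run
#'
#' Compares a pipeline result against the ground truth of the synthetic
#' study that generated its input.
#'
#' @param res A [run_srna_pipeline()] result.
#' @param truth The `sim_study`/`sim_truth` the reads came from.
#' @return List: `hairpin_sensitivity` (fraction of planted novel matures
#'   accepted), `novel_false` (accepted novel miRNAs not derived from a
#'   planted hairpin -- neither its mature nor its star arm -- as a
#'   fraction of accepted), `phase_recovery` (fraction of
#'   planted F/E/N miRNAs classified as their expected class),
#'   `phase_table` (per-miRNA detail), `category_accuracy` (fraction of
#'   reads from planted contaminant loci annotated to their class).
#' @export
evaluate_recovery <- function(res, truth) {
  planted <- truth$novel$seq
  found <- if (!is.null(res$novel)) res$novel$novel$seq else character(0)
  sens <- if (length(planted)) mean(planted %in% found) else NA_real_
  # a discovery is planted-derived if it is a planted mature or the star
  # arm of a planted hairpin (a genuine product of the planted precursor)
  from_planted <- c(planted, truth$novel$star)
  fdr <- if (length(found)) mean(!found %in% from_planted) else 0

  ids <- names(truth$expected_class)[truth$planted_class %in% c("F", "E", "N")]
  # novel ids surface under their discovered oru names: map via sequence
  id_map <- stats::setNames(ids, ids)
  if (!is.null(res$novel) && nrow(res$novel$novel)) {
    nov <- match(truth$novel$seq, res$novel$novel$seq)
    has <- !is.na(nov)
    id_map[truth$novel$id[has]] <- res$novel$novel$id[nov[has]]
  }
  got <- stats::setNames(as.character(res$phase$phase), res$phase$mirna_id)
  detail <- data.frame(
    id = ids,
    expected = as.character(truth$expected_class[ids]),
    observed = unname(got[id_map[ids]]),
    stringsAsFactors = FALSE)
  detail$observed[is.na(detail$observed)] <- "absent"
  recov <- mean(detail$observed == detail$expected)

  # category accuracy on contaminant-locus tags
  cls <- c("rRNA", "tRNA", "snRNA", "snoRNA", "scRNA", "repeat")
  annot <- res$annot
  acc <- NA_real_
  loci <- truth$features[truth$features$class %in% cls]
  if (length(loci) && nrow(annot)) {
    all_loci <- hits_granges(res$tags)
    ov <- GenomicRanges::findOverlaps(all_loci, loci, ignore.strand = TRUE)
    hit_tag <- res$tags$hits$tag[S4Vectors::queryHits(ov)]
    hit_cls <- as.character(loci$class)[S4Vectors::subjectHits(ov)]
    first <- !duplicated(hit_tag)
    truth_cls <- stats::setNames(hit_cls[first],
                                 res$tags$seq[hit_tag[first]])
    sel <- annot$seq %in% names(truth_cls)
    if (any(sel)) {
      acc <- mean(as.character(annot$category[sel]) ==
                    truth_cls[annot$seq[sel]])
    }
  }
  list(hairpin_sensitivity = sens, novel_false = fdr,
       phase_recovery = recov, phase_table = detail,
       category_accuracy = acc)
}
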