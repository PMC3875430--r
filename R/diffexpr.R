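# Between-library differential expression for unreplicated count libraries:
# reads-per-million normalization with a floor for absent miRNAs, log2
# fold-change, a conditional (Audic-Claverie) count test, significance
# labels, the low-count filter, and the flowering-phase (F/E/N) classifier.

#' Differential-expression configuration
#'
#' @param floor Normalized-expression substitute for miRNAs absent from one
#'   library (default 0.01 RPM).
#' @param fc_threshold Absolute log2 fold-change bound; both significance
#'   labels require `|log2fc| > fc_threshold`.
#' @param alpha_star,alpha_dstar P-value brackets: `*` for
#'   `alpha_dstar <= p < alpha_star`, `**` for `p < alpha_dstar`
#'   (strict inequalities; boundary values fall in the less significant
#'   bin).
#' @param scale Reads-per-million constant.
#' @return Named list.
#' @export
de_config <- function(floor = 0.01, fc_threshold = 1,
                      alpha_star = 0.05, alpha_dstar = 0.01,
                      scale = 1e6) {
  if (floor <= 0) stopf("floor must be positive")
  if (alpha_dstar >= alpha_star) stopf("need alpha_dstar < alpha_star")
  if (scale <= 0) stopf("scale must be positive")
  list(floor = floor, fc_threshold = fc_threshold,
       alpha_star = alpha_star, alpha_dstar = alpha_dstar, scale = scale)
}

#' Normalize a count to reads per million
#'
#' `count / total_clean * 1e6`; a zero count returns the configured floor so
#' fold-changes stay defined for miRNAs absent from one library.
#'
#' @param count Non-negative counts.
#' @param total_clean Positive clean-read total of the library.
#' @param config A [de_config()].
#' @return Normalized expression (RPM), floored.
#' @export
normalize_rpm <- function(count, total_clean, config = de_config()) {
  if (any(total_clean <= 0)) stopf("total_clean must be > 0")
  if (any(count < 0)) stopf("counts must be non-negative")
  rpm <- count / total_clean * config$scale
  rpm[count == 0] <- config$floor
  rpm
}

#' Log2 fold-change of normalized expression
#'
#' @param norm_a,norm_b Positive normalized expression in the two libraries
#'   (the floor guarantees positivity). Antisymmetric under pair swap.
#' @return `log2(norm_b / norm_a)`.
#' @export
log2_fold_change <- function(norm_a, norm_b) {
  if (any(norm_a <= 0) || any(norm_b <= 0)) {
    stopf("normalized expression must be positive (apply the floor first)")
  }
  log2(norm_b / norm_a)
}

#' Conditional count test between two libraries
#'
#' The probability of observing `y` counts in a library of `N2` clean reads
#' conditional on `x` counts in a library of `N1` clean reads, under equal
#' underlying proportions, is the Audic-Claverie distribution
#' `p(y|x) = (N2/N1)^y (x+y)! / (x! y! (1+N2/N1)^(x+y+1))`, i.e. a negative
#' binomial with size `x+1` and success probability `N1/(N1+N2)`. The
#' two-sided P reported here is `min(1, m1 + m2)`, where `m_d` is the
#' smaller of the lower and upper tails (each including the observed
#' point) conditioning in each direction; this form is symmetric under
#' swapping the libraries and reduces to the usual tail doubling in the
#' symmetric case. Tails are computed in log space via [stats::pnbinom].
#'
#' @param x,y Observed counts (non-negative, vectorized).
#' @param N1,N2 Positive clean-read totals.
#' @return P-values in (0, 1].
#' @export
count_test_pvalue <- function(x, N1, y, N2) {
  if (any(x < 0) || any(y < 0)) stopf("counts must be non-negative")
  if (any(N1 <= 0) || any(N2 <= 0)) stopf("library totals must be positive")
  m1 <- min_tail(x, N1, y, N2)
  m2 <- min_tail(y, N2, x, N1)
  pmin(1, m1 + m2)
}

# min(lower, upper) tail of y | x under the conditional NB, both tails
# including the observed point.
min_tail <- function(x, N1, y, N2) {
  prob <- N1 / (N1 + N2)
  lower <- stats::pnbinom(y, size = x + 1, prob = prob)
  upper <- stats::pnbinom(y - 1, size = x + 1, prob = prob,
                          lower.tail = FALSE)
  pmin(lower, upper)
}

#' Significance label for one comparison
#'
#' `**` for `|log2fc| > fc_threshold` and `p < alpha_dstar`; `*` for
#' `|log2fc| > fc_threshold` and `alpha_dstar <= p < alpha_star`; `ns`
#' otherwise. The fold-change bound applies to both labels.
#'
#' @param log2fc Log2 fold-changes.
#' @param pvalue P-values.
#' @param config A [de_config()].
#' @return Character vector over `{"ns", "*", "**"}`.
#' @export
de_label <- function(log2fc, pvalue, config = de_config()) {
  big <- abs(log2fc) > config$fc_threshold
  out <- rep("ns", length(log2fc))
  out[big & pvalue < config$alpha_dstar] <- "**"
  out[big & pvalue >= config$alpha_dstar & pvalue < config$alpha_star] <- "*"
  out
}

#' Low-count filter
#'
#' A miRNA is excluded from difference analysis iff its raw count is at or
#' below `threshold` in every library (too weak for a meaningful P-value).
#'
#' @param counts Count matrix (miRNAs x libraries).
#' @param threshold Per-library weak-expression bound (default 20 reads).
#' @return Logical vector: `TRUE` = retained.
#' @export
low_count_filter <- function(counts, threshold = 20L) {
  apply(as.matrix(counts) > threshold, 1L, any)
}

#' Pairwise differential expression table
#'
#' @param counts Count matrix (miRNAs x libraries); column names must match
#'   `libs$name`.
#' @param libs A [library_spec()] carrying the clean-read totals.
#' @param pairs Two-column character matrix of library pairs (A, B); by
#'   default every unordered pair in column order.
#' @param config A [de_config()].
#' @return data.frame: `mirna_id`, `lib_a`, `lib_b`, `count_a`, `count_b`,
#'   `norm_a`, `norm_b`, `log2fc` (B over A), `pvalue`, `label`.
#' @export
de_table <- function(counts, libs, pairs = NULL, config = de_config()) {
  counts <- as.matrix(counts)
  if (!all(colnames(counts) %in% libs$name)) {
    stopf("count columns missing from the library spec")
  }
  tot <- stats::setNames(libs$total_clean_reads, libs$name)
  if (any(is.na(tot[colnames(counts)]))) {
    stopf("library spec lacks clean-read totals")
  }
  if (is.null(pairs)) {
    pairs <- t(utils::combn(colnames(counts), 2L))
  }
  out <- lapply(seq_len(nrow(pairs)), function(r) {
    a <- pairs[r, 1L]; b <- pairs[r, 2L]
    na <- normalize_rpm(counts[, a], tot[[a]], config)
    nb <- normalize_rpm(counts[, b], tot[[b]], config)
    fc <- log2_fold_change(na, nb)
    p <- count_test_pvalue(counts[, a], tot[[a]], counts[, b], tot[[b]])
    data.frame(mirna_id = rownames(counts), lib_a = a, lib_b = b,
               count_a = counts[, a], count_b = counts[, b],
               norm_a = na, norm_b = nb, log2fc = fc, pvalue = p,
               label = de_label(fc, p, config),
               stringsAsFactors = FALSE, row.names = NULL)
  })
  do.call(rbind, out)
}

#' Classify miRNAs into flowering-phase classes
#'
#' Given the three pairwise significance calls among the two vegetative
#' libraries (V1: single-flowering group, V2: double-flowering group) and
#' the flowering library (F2: double-flowering group), a precedence chain
#' makes the classes exclusive and exhaustive over significant miRNAs:
#' `F` iff significant between V2 and F2 (flowering-related);
#' else `E` iff significant between V1 and F2 (early-flowering);
#' else `N` iff significant between V1 and V2;
#' else `unresolved`.
#'
#' @param sig_v1v2,sig_v1f2,sig_v2f2 Logical vectors ("significant" =
#'   label in `{"*", "**"}`), one element per miRNA, equal lengths.
#' @return Factor over `{"F", "E", "N", "unresolved"}`.
#' @export
classify_phase <- function(sig_v1v2, sig_v1f2, sig_v2f2) {
  n <- length(sig_v1v2)
  if (length(sig_v1f2) != n || length(sig_v2f2) != n) {
    stopf("all three pairwise significance vectors are required")
  }
  if (anyNA(sig_v1v2) || anyNA(sig_v1f2) || anyNA(sig_v2f2)) {
    stopf("missing pairwise significance call")
  }
  out <- rep("unresolved", n)
  out[sig_v1v2] <- "N"
  out[sig_v1f2] <- "E"
  out[sig_v2f2] <- "F"
  factor(out, levels = c("F", "E", "N", "unresolved"))
}

#' Phase classification from a differential-expression table
#'
#' Identifies the canonical three libraries from the spec (vegetative +
#' single-flowering = V1, vegetative + double-flowering = V2, flowering +
#' double-flowering = F2), extracts the three pairwise comparisons from a
#' [de_table()] result and applies [classify_phase()].
#'
#' @param de A [de_table()] result containing all three pairs.
#' @param libs The [library_spec()].
#' @return data.frame: `mirna_id`, the three significance flags, `phase`.
#' @export
phase_classification <- function(de, libs) {
  role <- function(stage, group) {
    nm <- libs$name[libs$stage == stage & libs$group == group]
    if (length(nm) != 1L) stopf("need exactly one %s/%s library", stage, group)
    nm
  }
  v1 <- role("vegetative", "single-flowering")
  v2 <- role("vegetative", "double-flowering")
  f2 <- role("flowering", "double-flowering")
  get_sig <- function(a, b) {
    sel <- (de$lib_a == a & de$lib_b == b) | (de$lib_a == b & de$lib_b == a)
    sub <- de[sel, , drop = FALSE]
    if (nrow(sub) == 0L) stopf("missing comparison %s vs %s", a, b)
    stats::setNames(sub$label %in% c("*", "**"), sub$mirna_id)
  }
  s12 <- get_sig(v1, v2); s1f <- get_sig(v1, f2); s2f <- get_sig(v2, f2)
  ids <- names(s12)
  if (!all(ids %in% names(s1f)) || !all(ids %in% names(s2f))) {
    stopf("the three comparisons cover different miRNA sets")
  }
  data.frame(mirna_id = ids,
             sig_v1v2 = unname(s12[ids]),
             sig_v1f2 = unname(s1f[ids]),
             sig_v2f2 = unname(s2f[ids]),
             phase = classify_phase(s12[ids], s1f[ids], s2f[ids]),
             stringsAsFactors = FALSE, row.names = NULL)
}
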