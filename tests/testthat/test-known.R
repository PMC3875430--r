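test_that("templated end-variant matching respects the +/-2 window", {
  toy <- toy_study()
  cat <- toy$catalog
  m <- toy$mature
  prec <- toy$prec
  s <- regexpr(m, prec, fixed = TRUE)[1L]
  e <- s + nchar(m) - 1L
  ext1 <- substr(prec, s, e + 1L)       # one templated 3' nt
  ext3 <- substr(prec, s, e + 3L)       # three nt: beyond the window
  trim2 <- substr(prec, s + 2L, e)      # 5' trim by 2

  tags <- collapse_reads(list(A = c(rep(m, 4L), rep(ext1, 2L), ext3, trim2)))
  rec <- match_known(tags, cat)
  get <- function(o5, o3) rec$count[rec$off5 == o5 & rec$off3 == o3]
  expect_equal(get(0L, 0L), 4L)
  expect_equal(get(0L, 1L), 2L)
  expect_equal(get(-2L, 0L), 1L)
  expect_false(ext3 %in% rec$seq)

  expr <- expression_matrix(rec, cat)
  expect_equal(unname(expr["toy-miR1", "A"]), 7L)  # raw = sum of variants
})

test_that("variant matching is symmetric in catalog order and never
           double-counts a tag", {
  set.seed(5)
  m1 <- rand_chr(21L); m2 <- rand_chr(21L)
  p1 <- paste0(rand_chr(10L), m1, rand_chr(10L))
  p2 <- paste0(rand_chr(10L), m2, rand_chr(10L))
  c12 <- mirna_catalog(c(a = m1, b = m2), c(pa = p1, pb = p2))
  c21 <- mirna_catalog(c(b = m2, a = m1), c(pb = p2, pa = p1))
  tags <- collapse_reads(list(L = c(rep(m1, 3L), rep(m2, 2L))))
  r12 <- match_known(tags, c12)
  r21 <- match_known(tags, c21)
  o <- function(r) r[order(r$mirna_id, r$seq), c("mirna_id", "seq", "count")]
  expect_equal(o(r12), o(r21), ignore_attr = TRUE)
  expect_equal(sum(r12$count), 5L)
})

test_that("isomiR recovery on simulated libraries is complete within +/-2", {
  sim <- get_sim()
  res <- get_pipeline()
  # every known_miRNA-category tag is matched, so known-category totals
  # equal the matched-record totals (module-boundary conservation)
  annot <- res$annot
  lib <- res$libspec$name[1L]
  cat_total <- sum(annot[[lib]][annot$category == "known_miRNA"])
  rec_total <- sum(res$known$records$count[res$known$records$library == lib])
  expect_equal(rec_total, cat_total)
})

test_that("family rollup conserves member sums and matches a group-by oracle", {
  set.seed(8)
  ids <- paste0("fam", rep(1:5, each = 2), letters[1:2])
  mats <- stats::setNames(vapply(1:10, function(i) rand_chr(21L), ""), ids)
  precs <- stats::setNames(
    vapply(mats, function(m) paste0(rand_chr(8L), m, rand_chr(8L)), ""),
    paste0(ids, "-p"))
  cat <- mirna_catalog(mats, precs)
  expr <- matrix(rpois(20L, 50), nrow = 10L,
                 dimnames = list(ids, c("L1", "L2")))
  fam <- family_rollup(expr, cat)
  oracle <- rowsum(expr, derive_family_oracle(ids))
  expect_equal(fam[order(rownames(fam)), ], oracle[order(rownames(oracle)), ])
  expect_equal(colSums(fam), colSums(expr))
})

test_that("star dominance is decided per library with ties to the mature", {
  mats <- c(m = "ACGTACGTACGTACGTACGTA", s = "TACGTACGTACGTACGTACGT")
  prec <- paste0("GG", mats[["m"]], "TTTT", mats[["s"]], "CC")
  cat <- mirna_catalog(mats, c(p = prec), star = c(m = "s"))
  expr <- matrix(c(1062L, 4312L,   # star dominates (published worked example)
                   10L, 0L,        # mature dominates
                   7L, 7L),        # tie: mature wins
                 nrow = 2L, dimnames = list(c("m", "s"), c("A", "B", "C")))
  expect_equal(detect_star_dominance(expr, cat, "A")$dominant, "star")
  expect_equal(detect_star_dominance(expr, cat, "B")$dominant, "mature")
  expect_equal(detect_star_dominance(expr, cat, "C")$dominant, "mature")
  expect_error(detect_star_dominance(expr, cat, "Z"), "unknown library")
})

test_that("first-base composition sums to one and recovers a planted bias", {
  expect_equal(first_base_composition(c("UAA", "UGG", "AGG", "CGG")),
               c(A = 0.25, C = 0.25, G = 0, U = 0.5))
  expect_equal(unname(first_base_composition("GAU")["G"]), 1)
  expect_error(first_base_composition(character(0)), "empty")

  set.seed(77)
  n <- 1e4
  first <- ifelse(runif(n) < 0.345, "T",
                  sample(c("A", "C", "G"), n, replace = TRUE))
  seqs <- paste0(first, "GG")
  fb <- first_base_composition(seqs)
  expect_equal(sum(fb), 1)
  expect_equal(unname(fb["U"]), 0.345, tolerance = 0.05)
})

test_that("stage/group occupancy classes partition the expressed universe", {
  libs <- library_spec(c("V1", "V2", "F2"),
                       c("vegetative", "vegetative", "flowering"),
                       c("single-flowering", "double-flowering",
                         "double-flowering"))
  set.seed(12)
  n <- 100L
  expr <- matrix(rbinom(3L * n, 1L, 0.6) * rpois(3L * n, 5L), ncol = 3L,
                 dimnames = list(paste0("m", 1:n), libs$name))
  part <- partition_by_stage_group(expr, libs)
  expect_equal(sum(part$sizes[c("vegetative_only", "flowering_only",
                                "both_stages")]),
               unname(part$sizes["universe"]))
  expect_equal(sum(part$sizes[c("single_only", "double_only",
                                "both_groups")]),
               unname(part$sizes["universe"]))
  # brute-force set algebra oracle
  inlib <- expr >= 1L
  veg <- rownames(expr)[inlib[, "V1"] | inlib[, "V2"]]
  flo <- rownames(expr)[inlib[, "F2"]]
  expect_setequal(part$stage$vegetative_only, setdiff(veg, flo))
  expect_setequal(part$stage$flowering_only, setdiff(flo, veg))
  expect_setequal(part$stage$both_stages, intersect(veg, flo))

  # a miRNA expressed in all libraries lands in both "both" classes
  all3 <- rownames(expr)[rowSums(inlib) == 3L]
  expect_true(all(all3 %in% part$stage$both_stages))
  expect_true(all(all3 %in% part$group$both_groups))
})

test_that("stem-loop assay design follows the length-plus-constant rule", {
  m21 <- "UGACAGAAGAGAGUGAGCACA"
  a <- design_stemloop_assay(m21)
  expect_equal(a$amplicon_length, 69L)
  expect_equal(design_stemloop_assay(paste0(m21, "A"))$amplicon_length, 70L)

  # RT primer 3' octamer base-pairs the miRNA 3' octamer 8/8
  tail8 <- substr(chartr("U", "T", m21), 14L, 21L)
  rt_oct <- substr(a$rt_primer, nchar(a$rt_primer) - 7L, nchar(a$rt_primer))
  expect_equal(rt_oct, revcomp_chr(tail8))
  # forward primer ends with the miRNA's first 10 nt
  expect_true(endsWith(a$forward_primer, substr(chartr("U", "T", m21), 1, 10)))

  expect_error(design_stemloop_assay("ACGUACGU"), "shorter|range")
  expect_error(design_stemloop_assay(strrep("A", 31L)), "range")
})
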