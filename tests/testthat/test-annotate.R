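test_that("collapse_reads conserves per-library counts", {
  r <- list(A = rep("ACGTACGTACGTACGTACGTA", 5L),
            B = c("ACGTACGTACGTACGTACGTA", "GGGTTTAAACCCGGGTTTAAA"))
  tags <- collapse_reads(r)
  expect_equal(length(tags$seq), 2L)
  i <- match("ACGTACGTACGTACGTACGTA", tags$seq)
  expect_equal(unname(tags$counts[i, "A"]), 5L)
  expect_equal(unname(colSums(tags$counts)), c(5L, 2L))

  # conservation on 10,000 simulated reads
  set.seed(31)
  pool <- vapply(1:300, function(i) rand_chr(sample(18:30, 1L)), "")
  reads <- list(L1 = sample(pool, 6000L, TRUE), L2 = sample(pool, 4000L, TRUE))
  tg <- collapse_reads(reads)
  expect_equal(unname(colSums(tg$counts)), c(6000L, 4000L))

  # out-of-range reads are dropped and reported
  tg2 <- collapse_reads(list(A = c("ACGT", strrep("A", 21L))))
  expect_equal(unname(tg2$n_dropped["A"]), 1L)
})

test_that("match_genome finds every perfect occurrence on both strands", {
  toy <- toy_study()
  g <- toy$genome_str
  plus_tag <- substr(g, 501L, 521L)
  minus_tag <- revcomp_chr(substr(g, 901L, 921L))
  set.seed(17)
  absent <- rand_chr(21L)  # random 21-mer, absent with high probability
  tags <- collapse_reads(list(A = c(plus_tag, minus_tag, absent)))
  tags <- match_genome(tags, toy$genome)

  i_plus <- match(plus_tag, tags$seq)
  h <- tags$hits[tags$hits$tag == i_plus, ]
  expect_true(any(h$strand == "+" & h$start == 501L))

  i_minus <- match(minus_tag, tags$seq)
  h2 <- tags$hits[tags$hits$tag == i_minus, ]
  expect_true(any(h2$strand == "-" & h2$start == 901L & h2$end == 921L))

  # brute-force scan oracle: occurrence counts on both strands agree
  cnt <- function(pat, s) {
    m <- gregexpr(pat, s, fixed = TRUE)[[1L]]
    if (m[1L] == -1L) 0L else length(m)
  }
  for (tg in c(plus_tag, minus_tag, absent)) {
    i <- match(tg, tags$seq)
    expect_equal(tags$n_loci[i], cnt(tg, g) + cnt(tg, revcomp_chr(g)))
  }
})

test_that("category assignment follows the filtering priority", {
  toy <- toy_study()
  g <- toy$genome_str
  rrna_read <- substr(g, toy$rrna_start, toy$rrna_start + 20L)
  exon_anti <- revcomp_chr(substr(g, toy$gene_start + 10L,
                                  toy$gene_start + 30L))
  mature <- toy$mature
  set.seed(23)
  tags <- collapse_reads(list(A = c(rrna_read, exon_anti, mature,
                                    rand_chr(22L))))
  tags <- match_genome(tags, toy$genome)
  annot <- assign_categories(tags, toy$tracks, toy$catalog)
  cat_of <- function(s) as.character(annot$category[annot$seq == s])

  expect_equal(cat_of(rrna_read), "rRNA")
  expect_equal(cat_of(exon_anti), "exon_antisense")
  expect_equal(cat_of(mature), "known_miRNA")

  # a tag overlapping both an rRNA track and an exon track goes to rRNA
  tracks2 <- toy$tracks
  tracks2$exon <- c(tracks2$exon, tracks2$rRNA)
  annot2 <- assign_categories(tags, tracks2, toy$catalog)
  expect_equal(as.character(annot2$category[annot2$seq == rrna_read]), "rRNA")

  # unknown priority entry is a config error
  expect_error(assign_categories(tags, toy$tracks, toy$catalog,
                                 priority = c("rRNA", "nosuch")),
               "unknown track name")
})

test_that("annotation is deterministic and order-independent", {
  sim <- get_sim()
  reads <- sim$reads
  tags1 <- match_genome(collapse_reads(reads), sim$genome)
  perm <- lapply(reads, function(r) rev(r))
  tags2 <- match_genome(collapse_reads(perm), sim$genome)
  a1 <- assign_categories(tags1, sim$tracks, sim$catalog)
  a2 <- assign_categories(tags2, sim$tracks, sim$catalog)
  expect_equal(a1$seq, a2$seq)
  expect_equal(a1$category, a2$category)
})

test_that("category reads partition the clean total exactly", {
  res <- get_pipeline()
  s <- res$category_summary
  for (lib in res$libspec$name) {
    reads_col <- s[[paste0(lib, "_reads")]]
    clean <- sum(res$tags$counts[res$tags$genome_matched, lib])
    expect_equal(sum(reads_col), clean)
    expect_equal(sum(s[[paste0(lib, "_pct")]]), 100, tolerance = 1e-9)
  }
})

test_that("summary percentages follow reads / total x 100", {
  one <- data.frame(seq = "ACGTACGTACGTACGTACGTA",
                    category = factor("rRNA", mirphase:::CATEGORY_LEVELS),
                    evidence = "x", A = 50L)
  s <- summarize_categories(one)
  expect_equal(s$A_pct[s$category == "rRNA"], 100)
  expect_error(category_percentages(matrix(1), 0), "positive")
})

test_that("length distribution sums to one and handles point masses", {
  t1 <- collapse_reads(list(A = rep(strrep("A", 21L), 4L)))
  ld <- length_distribution(t1)
  expect_equal(unname(ld["21", "A"]), 1)

  t2 <- collapse_reads(list(A = c(rep(strrep("AC", 10L), 3L),
                                  rep(strrep("GT", 12L), 3L))))
  ld2 <- length_distribution(t2)
  expect_equal(unname(ld2[c("20", "24"), "A"]), c(0.5, 0.5))

  sim <- get_sim()
  ld3 <- length_distribution(collapse_reads(sim$reads))
  mass2024 <- colSums(ld3[as.character(20:24), ])
  expect_true(all(mass2024 >= 0.6))
  expect_equal(unname(colSums(ld3)), rep(1, 3), tolerance = 1e-12)
})
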