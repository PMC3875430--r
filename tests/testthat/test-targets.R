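test_that("site scoring applies the seed-weighted penalty scheme", {
  m <- "UGACAGAAGAGAGUGAGCACA"                 # 21 nt
  site <- revcomp_chr(chartr("U", "T", m))     # perfect complement
  expect_equal(score_site(m, site)$expectation, 0)

  # one G:U wobble at miRNA position 20 -> 0.5 (outside the seed region):
  # target base opposite position 20 is site[2]; G:U means miRNA G on
  # target T, so set miRNA pos 20 to G and the target base to T
  m2 <- paste0(substr(m, 1, 19), "G", substr(m, 21, 21))
  site2 <- revcomp_chr(chartr("U", "T", m2))
  substr(site2, 2, 2) <- "T"
  expect_equal(score_site(m2, site2)$expectation, 0.5)

  # a mismatch at position 5 is doubled -> 2.0
  site3 <- site
  pos5 <- nchar(site3) - 5L + 1L
  comp5 <- substr(site3, pos5, pos5)
  repl <- setdiff(c("A", "C", "G", "T"),
                  c(comp5, "G", "T"))[1L]  # avoid creating a wobble
  substr(site3, pos5, pos5) <- repl
  expect_equal(score_site(m, site3)$expectation, 2.0)

  # ambiguous bases count as mismatches
  siteN <- site
  substr(siteN, 1L, 1L) <- "N"
  expect_equal(score_site(m, siteN)$expectation, 1.0)  # position 21, weight 1
})

test_that("the transcriptome scan reports planted sites exactly", {
  set.seed(6)
  m <- rand_chr(21L)
  site <- revcomp_chr(m)
  tr <- paste0(rand_chr(200L), site, rand_chr(200L))
  hits <- scan_targets(c(mir1 = m), c(t1 = tr), target_config())
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$start, 201L)
  expect_equal(hits$end, 221L)
  expect_equal(hits$expectation, 0)

  # the same site embedded twice -> two hits
  tr2 <- paste0(rand_chr(100L), site, rand_chr(80L), site, rand_chr(100L))
  hits2 <- scan_targets(c(mir1 = m), c(t1 = tr2), target_config())
  expect_equal(nrow(hits2), 2L)
  expect_equal(hits2$start, c(101L, 202L))
})

test_that("the vectorized scanner agrees with the brute-force window oracle", {
  set.seed(14)
  cfg <- target_config(cutoff = 4)
  for (r in 1:50) {
    m <- rand_chr(sample(20:22, 1L))
    tr <- paste0(rand_chr(60L),
                 if (r %% 2L) revcomp_chr(m) else rand_chr(nchar(m)),
                 rand_chr(60L))
    # mutate the embedded site a little so near-threshold cases occur
    p <- sample.int(nchar(tr), 3L)
    for (q in p) substr(tr, q, q) <- sample(c("A", "C", "G", "T"), 1L)
    got <- scan_targets(c(x = m), c(t = tr), cfg, dedupe = FALSE)
    want <- scan_oracle(m, tr, cfg)
    got <- got[order(got$start, got$end), ]
    want <- want[order(want$start, want$end), ]
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_equal(got$expectation, want$expectation)
  }
})

test_that("lowering the cutoff never adds hits", {
  set.seed(15)
  m <- rand_chr(21L)
  tr <- paste0(rand_chr(300L), revcomp_chr(m), rand_chr(300L))
  h4 <- scan_targets(c(x = m), c(t = tr), target_config(cutoff = 4),
                     dedupe = FALSE)
  h2 <- scan_targets(c(x = m), c(t = tr), target_config(cutoff = 2),
                     dedupe = FALSE)
  expect_true(all(paste(h2$start, h2$end) %in% paste(h4$start, h4$end)))
  expect_lte(nrow(h2), nrow(h4))
})

test_that("the unweighted duplex penalty is reversal-invariant", {
  set.seed(16)
  cfg <- target_config(seed_mult = 1)   # disable position weighting
  revstr <- function(s) paste(rev(strsplit(s, "")[[1L]]), collapse = "")
  for (r in 1:20) {
    m <- rand_chr(21L)
    site <- rand_chr(21L)
    a <- score_site(m, site, cfg)$expectation
    b <- score_site(revstr(m), revstr(site), cfg)$expectation
    expect_equal(a, b)
  }
})

test_that("mean targets per miRNA uses miRNAs with at least one hit", {
  hits <- data.frame(mirna_id = c("a", "a", "a"))
  expect_equal(average_targets_per_mirna(hits), 3.0)
  expect_error(average_targets_per_mirna(hits[0, , drop = FALSE]), "no miRNA")
  set.seed(18)
  for (r in 1:10) {
    ids <- sample(letters[1:5], 30L, TRUE)
    h <- data.frame(mirna_id = ids)
    expect_equal(average_targets_per_mirna(h),
                 round(length(ids) / length(unique(ids)), 1L))
  }
})

test_that("flowering annotation joins ids and keywords", {
  fl <- read_flowering_genes(system.file("extdata", "flowering_genes.tsv",
                                         package = "mirphase"))
  hits <- data.frame(mirna_id = c("m1", "m1", "m2", "m3"),
                     transcript_id = c("synT-FT1", "t2", "t3", "t4"),
                     stringsAsFactors = FALSE)
  desc <- c(t2 = "unknown protein", t3 = "heading date regulator Hd1",
            t4 = "kinase")
  ann <- annotate_flowering(hits, fl, desc)
  expect_true(ann$hits$flowering_flag[1L])   # id join
  expect_true(ann$hits$flowering_flag[3L])   # keyword join
  expect_false(ann$hits$flowering_flag[4L])
  expect_setequal(ann$flowering_mirnas, c("m1", "m2"))
  expect_equal(ann$n_flowering, 2L)
})

test_that("cleavage mapping converts clone ends to miRNA bond positions", {
  hit <- list(transcript_id = "t1", start = 100L, end = 120L)  # 21-nt site
  clones <- data.frame(transcript_id = "t1",
                       position = c(111L, 116L, 105L, 300L),
                       count = c(5L, 2L, 1L, 4L))
  prof <- map_cleavage_sites(hit, clones)
  # clone end at 111 pairs the bond between miRNA positions 10 and 11
  expect_equal(prof$sites$label[prof$sites$position == 111L], "10-11")
  expect_equal(prof$modal, "10-11")           # highest count wins
  expect_equal(nrow(prof$off_site), 1L)       # position 300 is off-site
  expect_error(map_cleavage_sites(hit, data.frame(
    transcript_id = "t1", position = 111L, count = 0L)), "positive")

  # round-trip: plant a site, cleave at a chosen bond, recover it
  set.seed(19)
  m <- rand_chr(21L)
  tr <- paste0(rand_chr(150L), revcomp_chr(m), rand_chr(150L))
  h <- scan_targets(c(x = m), c(t = tr))
  bond <- 10L
  clone_pos <- h$end - bond + 1L
  prof2 <- map_cleavage_sites(as.list(h[1L, ]),
                              data.frame(transcript_id = "t",
                                         position = clone_pos, count = 3L))
  expect_equal(prof2$modal, "10-11")
})
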