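test_that("flank extraction returns the tag with clipped context", {
  toy <- toy_study()
  # a 20-nt tag mid-chromosome gives a 320-nt window
  loc <- GenomicRanges::GRanges("chr1", IRanges::IRanges(500L, 519L), "+")
  fl <- extract_flanks(loc, toy$genome)
  expect_equal(nchar(fl$seq), 320L)
  expect_equal(substr(fl$seq, fl$tag_start, fl$tag_start + 19L),
               substr(toy$genome_str, 500L, 519L))

  # near the chromosome start the window is clipped
  loc2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(10L, 29L), "+")
  fl2 <- extract_flanks(loc2, toy$genome)
  expect_equal(nchar(fl2$seq), 9L + 20L + 150L)
  expect_equal(fl2$tag_start, 10L)

  # minus-strand extraction is the reverse complement of the plus window
  loc3 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(500L, 519L), "-")
  fl3 <- extract_flanks(loc3, toy$genome)
  expect_equal(fl3$seq, revcomp_chr(fl$seq))
  expect_equal(substr(fl3$seq, fl3$tag_start, fl3$tag_start + 19L),
               revcomp_chr(substr(toy$genome_str, 500L, 519L)))
})

test_that("hairpin criteria accept planted duplexes and reject loop-spanners", {
  toy <- toy_study()
  loc <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(toy$mature_start,
                             toy$mature_start + nchar(toy$mature) - 1L), "+")
  fl <- extract_flanks(loc, toy$genome)
  cand <- hairpin_criteria(fl$seq, fl$tag_start, fl$tag_len)
  expect_true(cand$accepted)
  expect_equal(cand$duplex_mismatches, 0L)
  expect_equal(cand$mature_arm, "5p")
  # accepted mature is a perfect substring of its window
  expect_equal(substr(fl$seq, fl$tag_start, fl$tag_start + fl$tag_len - 1L),
               toy$mature)

  # a tag spanning the terminal loop is rejected with reason "arm"
  prec_mid <- toy$prec_start + nchar(toy$prec) %/% 2L
  loc2 <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(prec_mid - 10L, prec_mid + 10L), "+")
  fl2 <- extract_flanks(loc2, toy$genome)
  cand2 <- hairpin_criteria(fl2$seq, fl2$tag_start, fl2$tag_len)
  expect_false(cand2$accepted)
  expect_true("arm" %in% cand2$reasons)
})

test_that("acceptance is monotone in the thresholds", {
  set.seed(9)
  sim <- get_sim()
  res <- get_pipeline()
  cands <- res$novel$candidates
  loose <- hairpin_config(max_mismatch = 6L, max_bulge = 3L, mfe_max = -10)
  # re-evaluate every candidate window under looser thresholds
  for (i in seq_len(min(nrow(cands), 15L))) {
    i_tag <- match(cands$seq[i], res$tags$seq)
    loc <- tag_loci(res$tags, i_tag)[1L]
    fl <- extract_flanks(loc, sim$genome)
    strict <- hairpin_criteria(fl$seq, fl$tag_start, fl$tag_len)
    relax <- hairpin_criteria(fl$seq, fl$tag_start, fl$tag_len,
                              config = loose)
    if (strict$accepted) expect_true(relax$accepted)
  }
})

test_that("genomic context follows the UTR > junction > exon > intron
           precedence", {
  toy <- toy_study()
  gs <- toy$gene_start
  loci <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    c(gs + 5L,            # inside the UTR
      gs + 145L,          # straddles exon1/intron boundary
      gs + 100L,          # exon only
      gs + 200L,          # intron only
      5000L),             # nothing
    width = 21L), "+")
  ctx <- classify_context(loci, toy$tracks)
  expect_equal(ctx, c("UTR", "intron-exon junction", "exon", "intron",
                      "intergenic"))
})

test_that("multi-locus grouping merges identical matures order-independently", {
  base <- data.frame(
    seq = c("AAA", "AAA", "AAA", "CCC"),
    locus = c("chr1:1-3:+", "chr2:5-7:-", "chr3:9-11:+", "chr1:50-52:+"),
    stringsAsFactors = FALSE)
  g <- group_multilocus(base)
  expect_equal(nrow(g), 2L)
  expect_equal(g$n_loci[g$seq == "AAA"], 3L)
  expect_equal(g$id, c("oru-miR1", "oru-miR2"))

  set.seed(13)
  for (r in 1:20) {
    perm <- base[sample.int(nrow(base)), , drop = FALSE]
    gp <- group_multilocus(perm)
    expect_setequal(paste(gp$seq, gp$loci), paste(g$seq, g$loci))
  }
})

test_that("dinucleotide shuffling conserves composition exactly", {
  set.seed(21)
  for (r in 1:10) {
    s <- rand_chr(120L)
    sh <- dinucleotide_shuffle(s)
    expect_equal(nchar(sh), nchar(s))
    expect_equal(dinuc_counts(sh), dinuc_counts(s))
    expect_equal(substr(sh, 1L, 1L), substr(s, 1L, 1L))
  }
})

test_that("shuffled windows are rejected at a low rate and planted hairpins
           are always recovered", {
  sim <- get_sim()
  res <- get_pipeline()
  rec <- evaluate_recovery(res, sim)
  expect_equal(rec$hairpin_sensitivity, 1.0)
  expect_lte(rec$novel_false, 0.05)

  # dinucleotide-shuffle null: the acceptance machinery fires rarely
  set.seed(42)
  cfg <- hairpin_config()
  novel_loci <- sim$features[sim$features$class == "novel_prec"]
  n_acc <- 0L; n <- 200L
  for (r in seq_len(n)) {
    loc <- novel_loci[(r - 1L) %% length(novel_loci) + 1L]
    fl <- extract_flanks(loc, sim$genome)
    shuf <- dinucleotide_shuffle(fl$seq)
    ts <- sample.int(nchar(shuf) - 21L, 1L)
    cand <- hairpin_criteria(shuf, ts, 21L, config = cfg)
    n_acc <- n_acc + cand$accepted
  }
  expect_lte(n_acc / n, 0.05)
})
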