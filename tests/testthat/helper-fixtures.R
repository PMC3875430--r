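# Shared fixtures and independent oracles for the test suite.

.fixtures <- new.env(parent = emptyenv())

# The default synthetic study (seed 1) and one full pipeline run over it,
# built once per test session.
get_sim <- function() {
  if (is.null(.fixtures$sim)) {
    .fixtures$sim <- simulate_srna_study(sim_config(seed = 1))
  }
  .fixtures$sim
}

get_pipeline <- function() {
  if (is.null(.fixtures$res)) {
    sim <- get_sim()
    .fixtures$res <- run_srna_pipeline(sim$reads, sim$genome, sim$tracks,
                                       sim$catalog, sim$libspec)
  }
  .fixtures$res
}

# A small hand-built genome with one planted hairpin, one rRNA locus and
# one two-exon gene, for unit tests that need full control.
toy_study <- function() {
  set.seed(99)
  mature <- "TGAGGTAGTAGGTTGTATAGTT"                      # 22 nt
  arm5 <- paste0(rand_chr(8), mature, rand_chr(6))
  prec <- paste0(arm5, rand_chr(8), revcomp_chr(arm5))
  left <- rand_chr(400)
  rrna <- rand_chr(120)
  exon1 <- rand_chr(150); intron <- rand_chr(120); exon2 <- rand_chr(150)
  right <- rand_chr(400)
  genome_str <- paste0(left, prec, rand_chr(200), rrna, rand_chr(200),
                       exon1, intron, exon2, right)
  genome <- Biostrings::DNAStringSet(genome_str)
  names(genome) <- "chr1"
  prec_start <- nchar(left) + 1L
  rrna_start <- nchar(left) + nchar(prec) + 200L + 1L
  gene_start <- rrna_start + 120L + 200L
  tracks <- list(
    rRNA = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(rrna_start, rrna_start + 119L), "+"),
    exon = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(c(gene_start, gene_start + 270L),
                       c(gene_start + 149L, gene_start + 419L)), "+"),
    intron = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(gene_start + 150L, gene_start + 269L), "+"),
    utr = GenomicRanges::GRanges("chr1",
      IRanges::IRanges(gene_start, gene_start + 39L), "+"))
  catalog <- mirna_catalog(c(`toy-miR1` = mature),
                           c(`toy-miR1-prec` = prec))
  list(genome = genome, genome_str = genome_str, tracks = tracks,
       catalog = catalog, mature = mature, prec = prec,
       prec_start = prec_start, mature_start = prec_start + 8L,
       rrna_start = rrna_start, gene_start = gene_start)
}

rand_chr <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

revcomp_chr <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# ---- independent oracles ---------------------------------------------------

# Audic-Claverie tails by direct term-by-term enumeration (log-space),
# independent of the pnbinom implementation path.
ac_oracle <- function(x, N1, y, N2) {
  lp <- function(k, x, N1, N2) {
    k * log(N2 / N1) + lchoose(x + k, k) - (x + k + 1) * log1p(N2 / N1)
  }
  tails <- function(x, N1, y, N2) {
    lower <- sum(exp(lp(0:y, x, N1, N2)))
    k <- y; s <- 0
    repeat {
      t <- exp(lp(k, x, N1, N2)); s <- s + t; k <- k + 1
      if ((t < s * 1e-17 && k > y + 10) || k > y + 200000) break
    }
    min(lower, s)
  }
  min(1, tails(x, N1, y, N2) + tails(y, N2, x, N1))
}

# Exhaustive window-by-window target scan through score_site().
scan_oracle <- function(mirna, transcript, config = target_config()) {
  L <- nchar(mirna); n <- nchar(transcript)
  rows <- list()
  for (W in (L - 1L):(L + 1L)) {
    if (W < 3L || W > n) next
    for (s in seq_len(n - W + 1L)) {
      win <- substr(transcript, s, s + W - 1L)
      sc <- score_site(mirna, win, config)
      if (!is.null(sc) && sc$expectation <= config$cutoff) {
        rows[[length(rows) + 1L]] <- data.frame(
          start = s, end = s + W - 1L, expectation = sc$expectation)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      expectation = numeric(0)))
  }
  do.call(rbind, rows)
}

# Independent family derivation (strip the trailing member letter).
derive_family_oracle <- function(ids) sub("[a-z]$", "", ids)

# Count dinucleotides of a sequence (for shuffle conservation checks).
dinuc_counts <- function(s) {
  ch <- strsplit(s, "")[[1L]]
  table(paste0(ch[-length(ch)], ch[-1L]))
}
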