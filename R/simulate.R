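# Synthetic study generator: a toy genome with planted structural-RNA,
# repeat and gene loci, a known-miRNA catalog with hairpin precursors and
# star partners, novel hairpins, and three unreplicated read libraries
# (two vegetative, one flowering) with negative-binomial counts and planted
# fold-change effects carrying ground-truth F/E/N phase labels.

#' Simulation configuration
#'
#' Defaults emulate the study design the package targets: three libraries
#' (vegetative single-flowering V1, vegetative double-flowering V2,
#' flowering double-flowering F2), 18-30 nt reads with >= 60% of read mass
#' on 20-24 nt and a 21-nt mode, a 5'-U bias of 0.345, an rRNA-dominated
#' contaminant background, and negative-binomial counts (size 100, mild
#' overdispersion) at 1e5 reads per library.
#'
#' @param seed Mandatory integer seed; the whole study is a deterministic
#'   function of the configuration.
#' @param genome_length Genome size, nt.
#' @param depth Nominal reads per library.
#' @param dispersion Negative-binomial size parameter.
#' @param n_known,n_novel Number of planted known matures / novel hairpins.
#' @param n_genes Number of exon-intron genes.
#' @param length_profile Named probabilities over read lengths 18-30.
#' @param mature_len_probs Named probabilities over mature lengths 20-24.
#' @param five_prime_u_bias Probability that a planted mature starts with U.
#' @param isomir_rate Fraction of known-miRNA reads emitted as templated
#'   +/-1-2-nt end variants.
#' @param class_share Named read-mass proportions per contaminant class
#'   (plus `background` intergenic reads and genome-`unmatched` junk).
#' @param effects Planted per-class fold multipliers, see
#'   [default_effects()].
#' @return Named list of class `sim_config`.
#' @export
sim_config <- function(seed,
                       genome_length = 200000L,
                       depth = 1e5,
                       dispersion = 100,
                       n_known = 40L,
                       n_novel = 12L,
                       n_genes = 6L,
                       length_profile = default_length_profile(),
                       mature_len_probs = c(`20` = 0.15, `21` = 0.50,
                                            `22` = 0.15, `23` = 0.10,
                                            `24` = 0.10),
                       five_prime_u_bias = 0.345,
                       isomir_rate = 0.15,
                       class_share = default_class_share(),
                       effects = default_effects()) {
  if (missing(seed)) stopf("seed is mandatory")
  stopifnot(abs(sum(length_profile) - 1) < 1e-8,
            abs(sum(mature_len_probs) - 1) < 1e-8)
  structure(list(seed = as.integer(seed), genome_length = genome_length,
                 depth = depth, dispersion = dispersion, n_known = n_known,
                 n_novel = n_novel, n_genes = n_genes,
                 length_profile = length_profile,
                 mature_len_probs = mature_len_probs,
                 five_prime_u_bias = five_prime_u_bias,
                 isomir_rate = isomir_rate, class_share = class_share,
                 effects = effects),
            class = "sim_config")
}

#' @rdname sim_config
#' @export
default_length_profile <- function() {
  p <- c(`18` = 0.02, `19` = 0.03, `20` = 0.08, `21` = 0.27, `22` = 0.14,
         `23` = 0.12, `24` = 0.13, `25` = 0.06, `26` = 0.05, `27` = 0.04,
         `28` = 0.03, `29` = 0.02, `30` = 0.01)
  p / sum(p)
}

#' @rdname sim_config
#' @export
default_class_share <- function() {
  c(rRNA = 0.40, tRNA = 0.08, snRNA = 0.003, snoRNA = 0.003, scRNA = 0.002,
    `repeat` = 0.10, exon_sense = 0.02, exon_antisense = 0.008,
    intron_sense = 0.012, intron_antisense = 0.006,
    background = 0.10, unmatched = 0.02)
}

#' Planted expression effects
#'
#' Multipliers are applied to the per-library expected counts of planted
#' known miRNAs. F-miRNAs change between V2 and F2 (flowering transition of
#' the double-flowering group); E-miRNAs are shifted in both double-flowering
#' libraries relative to V1 (early-flowering difference between groups);
#' N-miRNAs differ only between the two vegetative libraries, with F2
#' placed between them so neither flowering comparison crosses the
#' fold-change bound. Half of each class is up-, half down-regulated so
#' library read masses stay balanced. Stage-exclusive miRNAs (multiplier 0)
#' exercise the occupancy partitions.
#'
#' @param n_F,n_E,n_N Planted class sizes.
#' @param n_veg_only,n_flow_only Stage-exclusive miRNA counts.
#' @param fc Primary fold effect (F and E classes).
#' @param fc_N Vegetative-stage fold effect for N-miRNAs (its square root
#'   places F2 between V1 and V2).
#' @param base_prop Base per-library read proportion of each planted miRNA.
#' @return data.frame with one row per planted miRNA slot: `class`,
#'   `direction`, multipliers `m_v1`, `m_v2`, `m_f2`, `base_prop`.
#' @export
default_effects <- function(n_F = 12L, n_E = 6L, n_N = 4L,
                            n_veg_only = 3L, n_flow_only = 3L,
                            fc = 6, fc_N = 2.6, base_prop = 0.002) {
  half <- function(n) rep(c(1, -1), length.out = n)
  mk <- function(class, d, v1, v2, f2) {
    if (length(d) == 0L) return(NULL)
    data.frame(class = class, direction = d, m_v1 = v1, m_v2 = v2, m_f2 = f2)
  }
  dF <- half(n_F); dE <- half(n_E); dN <- half(n_N)
  rows <- list(
    mk("F", dF, 1, 1, fc^dF),
    mk("E", dE, 1, fc^dE, fc^dE),
    mk("N", dN, 1, fc_N^dN, sqrt(fc_N)^dN),
    mk("veg_only", rep(0, n_veg_only), 1, 1, 0),
    mk("flow_only", rep(0, n_flow_only), 0, 0, 1))
  rows <- rows[!vapply(rows, is.null, TRUE)]
  if (!length(rows)) {
    out <- data.frame(class = character(0), direction = numeric(0),
                      m_v1 = numeric(0), m_v2 = numeric(0),
                      m_f2 = numeric(0))
    out$base_prop <- numeric(0)
    return(out)
  }
  out <- do.call(rbind, rows)
  out$base_prop <- ifelse(out$class %in% c("veg_only", "flow_only"),
                          base_prop / 2, base_prop)
  rownames(out) <- NULL
  out
}

rand_seq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rand_mature <- function(len, u_bias) {
  first <- if (stats::runif(1) < u_bias) "T" else sample(c("A", "C", "G"), 1L)
  paste0(first, rand_seq(len - 1L))
}

# Perfect-stem hairpin: pad5 + mature + pad3 | loop | reverse complement.
make_hairpin <- function(mature, pad5 = 8L, pad3 = 6L, loop_len = 8L) {
  arm5 <- paste0(rand_seq(pad5), mature, rand_seq(pad3))
  list(prec = paste0(arm5, rand_seq(loop_len), revcomp(arm5)),
       mature_offset = pad5 + 1L,
       star = revcomp(mature))
}

# Non-overlapping random placement with a safety gap.
place_features <- function(lengths, genome_length, gap = 35L) {
  starts <- integer(length(lengths))
  occupied <- matrix(numeric(0), ncol = 2L)
  for (i in seq_along(lengths)) {
    placed <- FALSE
    for (try in 1:2000) {
      s <- sample.int(genome_length - lengths[i] - gap, 1L) + gap
      e <- s + lengths[i] - 1L
      if (!nrow(occupied) ||
          all(e + gap < occupied[, 1L] | s - gap > occupied[, 2L])) {
        occupied <- rbind(occupied, c(s, e))
        starts[i] <- s
        placed <- TRUE
        break
      }
    }
    if (!placed) stopf("genome too small to place features; increase genome_length")
  }
  starts
}

#' Build the synthetic genome, tracks, catalog and ground truth
#'
#' Plants all features at non-overlapping loci (contaminants, exon/intron
#' genes, known-miRNA precursors with star partners, novel hairpins --
#' novel hairpins are intergenic so that the annotation cascade leaves
#' their reads unannotated). Every planted novel hairpin is fold-checked
#' against the builtin engine and the default acceptance criteria before
#' emission; hairpins are re-drawn until they conform.
#'
#' @param config A [sim_config()]. Calling this function seeds the RNG
#'   from `config$seed`.
#' @return List of class `sim_truth`: `genome` (DNAStringSet), `tracks`
#'   (named list of GRanges incl. `utr`), `catalog` ([mirna_catalog()]),
#'   `novel` (data.frame id/seq/star/locus), `features` (GRanges of all
#'   planted loci with `id`, `class` metadata), `mirna_prop` (base
#'   proportions), `mult` (multiplier matrix, rows = mirna/novel ids),
#'   `planted_class`, `expected_class` (see [expected_phase_truth()]),
#'   `libspec`, `config`.
#' @export
build_genome <- function(config) {
  set.seed(config$seed)
  libs <- library_spec(c("CWR-V1", "CWR-V2", "CWR-F2"),
                       c("vegetative", "vegetative", "flowering"),
                       c("single-flowering", "double-flowering",
                         "double-flowering"))

  cont_spec <- list(rRNA = c(6L, 150L), tRNA = c(8L, 75L), snRNA = c(4L, 110L),
                    snoRNA = c(4L, 90L), scRNA = c(2L, 120L),
                    `repeat` = c(10L, 250L))

  eff <- config$effects
  n_planted <- nrow(eff)
  if (config$n_known < n_planted) {
    stopf("n_known (%d) smaller than the planted effect table (%d rows)",
          config$n_known, n_planted)
  }
  n_null <- config$n_known - n_planted

  # --- known matures, families, stars -------------------------------------
  fam_of <- integer(0)
  for (f in seq_len(config$n_known)) {      # first 10 families get 2 members
    fam_of <- c(fam_of, rep(f, if (f <= 10L) 2L else 1L))
    if (length(fam_of) >= config$n_known) break
  }
  fam_of <- fam_of[seq_len(config$n_known)]
  member <- stats::ave(fam_of, fam_of, FUN = seq_along)
  known_ids <- paste0("syn-miR", fam_of, letters[member])

  lens <- as.integer(sample(names(config$mature_len_probs), config$n_known,
                            replace = TRUE, prob = config$mature_len_probs))
  known_seq <- vapply(lens, rand_mature, "", u_bias = config$five_prime_u_bias)
  while (anyDuplicated(known_seq)) {        # vanishing probability, be safe
    i <- which(duplicated(known_seq))[1L]
    known_seq[i] <- rand_mature(lens[i], config$five_prime_u_bias)
  }
  names(known_seq) <- known_ids

  hp <- lapply(known_seq, make_hairpin)
  prec_seq <- vapply(hp, `[[`, "", "prec")
  prec_ids <- paste0(known_ids, "-prec")
  names(prec_seq) <- prec_ids

  # star partners: 6 ordinary + 2 star-dominant, attached to null matures
  null_ids <- known_ids[seq(n_planted + 1L, config$n_known)]
  star_host <- null_ids[seq_len(min(8L, length(null_ids)))]
  star_ids <- paste0(star_host, "*")
  star_seq <- stats::setNames(vapply(hp[star_host], `[[`, "", "star"),
                              star_ids)

  matures_all <- c(known_seq, star_seq)
  star_links <- stats::setNames(star_ids, star_host)

  # --- novel hairpins ------------------------------------------------------
  novel_ids <- paste0("nov", seq_len(config$n_novel))
  novel_len <- as.integer(sample(names(config$mature_len_probs),
                                 config$n_novel, replace = TRUE,
                                 prob = config$mature_len_probs))
  novel_mature <- vapply(novel_len, rand_mature, "",
                         u_bias = config$five_prime_u_bias)
  novel_hp <- lapply(novel_mature, make_hairpin)
  novel_prec <- vapply(novel_hp, `[[`, "", "prec")

  # --- genome layout -------------------------------------------------------
  gene_struct <- c(exon = 300L, intron = 250L, exon = 250L, intron = 200L,
                   exon = 200L)
  feat_class <- c(rep(names(cont_spec), vapply(cont_spec, `[`, 0L, 1L)),
                  rep("gene", config$n_genes),
                  rep("known_prec", config$n_known),
                  rep("novel_prec", config$n_novel))
  feat_len <- c(rep(vapply(cont_spec, `[`, 0L, 2L),
                    vapply(cont_spec, `[`, 0L, 1L)),
                rep(sum(gene_struct), config$n_genes),
                nchar(prec_seq), nchar(novel_prec))
  feat_id <- c(unlist(lapply(names(cont_spec), function(cl) {
    paste0(cl, seq_len(cont_spec[[cl]][1L]))
  })), paste0("gene", seq_len(config$n_genes)), prec_ids,
  paste0(novel_ids, "-prec"))

  starts <- place_features(feat_len, config$genome_length)
  strand <- sample(c("+", "-"), length(feat_len), replace = TRUE)
  genome_chars <- strsplit(rand_seq(config$genome_length), "")[[1L]]

  insert <- function(seq, s, str) {
    if (str == "-") seq <- revcomp(seq)
    genome_chars[s:(s + nchar(seq) - 1L)] <<- strsplit(seq, "")[[1L]]
  }
  is_prec <- feat_class %in% c("known_prec", "novel_prec")
  all_prec_seq <- c(prec_seq, stats::setNames(novel_prec,
                                              paste0(novel_ids, "-prec")))
  for (k in which(is_prec)) {
    insert(all_prec_seq[[feat_id[k]]], starts[k], strand[k])
  }
  genome_str <- paste(genome_chars, collapse = "")
  genome <- Biostrings::DNAStringSet(genome_str)
  names(genome) <- "chr1"

  features <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(starts, starts + feat_len - 1L), strand,
    id = feat_id, class = feat_class,
    seqlengths = c(chr1 = config$genome_length))

  # --- tracks --------------------------------------------------------------
  tracks <- list()
  for (cl in names(cont_spec)) {
    tracks[[cl]] <- features[features$class == cl]
  }
  exon <- intron <- utr <- GenomicRanges::GRanges()
  for (k in which(feat_class == "gene")) {
    offs <- cumsum(c(0L, gene_struct[-length(gene_struct)]))
    seg <- GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(starts[k] + offs,
                               starts[k] + offs + gene_struct - 1L),
      strand[k], gene = feat_id[k])
    ex <- seg[names(gene_struct) == "exon"]
    exon <- c(exon, ex)
    intron <- c(intron, seg[names(gene_struct) == "intron"])
    # terminal 60 nt of the transcript ends are UTR (strand-aware)
    first_ex <- ex[1L]; last_ex <- ex[length(ex)]
    if (strand[k] == "+") {
      u5 <- GenomicRanges::resize(first_ex, 60L, fix = "start")
      u3 <- GenomicRanges::resize(last_ex, 60L, fix = "end")
    } else {
      u5 <- GenomicRanges::resize(last_ex, 60L, fix = "start")
      u3 <- GenomicRanges::resize(first_ex, 60L, fix = "end")
    }
    utr <- c(utr, u5, u3)
  }
  tracks$exon <- exon; tracks$intron <- intron; tracks$utr <- utr

  catalog <- mirna_catalog(matures_all, prec_seq, star = star_links,
                           prec_loci = features[match(prec_ids, features$id)])

  # --- validate planted novel hairpins against the acceptance criteria -----
  cfg_h <- hairpin_config()
  novel_loci <- features[match(paste0(novel_ids, "-prec"), features$id)]
  for (j in seq_len(config$n_novel)) {
    for (try in 1:20) {
      ok <- novel_conforms(novel_mature[j], novel_hp[[j]], novel_loci[j],
                           genome, cfg_h)
      if (ok) break
      # re-draw this hairpin in place
      novel_mature[j] <- rand_mature(novel_len[j], config$five_prime_u_bias)
      novel_hp[[j]] <- make_hairpin(novel_mature[j])
      k <- which(feat_id == paste0(novel_ids[j], "-prec"))
      pseq <- novel_hp[[j]]$prec
      if (nchar(pseq) != feat_len[k]) next  # length must match the slot
      gs <- if (strand[k] == "-") revcomp(pseq) else pseq
      substr(genome_str, starts[k], starts[k] + nchar(pseq) - 1L) <- gs
      genome <- Biostrings::DNAStringSet(genome_str)
      names(genome) <- "chr1"
    }
    if (!ok) stopf("could not plant a conforming novel hairpin (slot %d)", j)
  }

  # --- expression model ----------------------------------------------------
  mult <- matrix(1, nrow = config$n_known + length(star_ids) + config$n_novel,
                 ncol = 3L,
                 dimnames = list(c(known_ids, star_ids, novel_ids),
                                 libs$name))
  mult[seq_len(n_planted), ] <- as.matrix(eff[c("m_v1", "m_v2", "m_f2")])
  # stars follow their host's (null) multipliers: already 1
  # a few novel miRNAs are single-library to exercise occupancy classes
  if (config$n_novel >= 3L) {
    mult[novel_ids[1L], c("CWR-V2", "CWR-F2")] <- 0
    mult[novel_ids[2L], c("CWR-V1", "CWR-F2")] <- 0
    mult[novel_ids[3L], c("CWR-V1", "CWR-V2")] <- 0
  }

  prop <- stats::setNames(numeric(nrow(mult)), rownames(mult))
  prop[seq_len(n_planted)] <- eff$base_prop
  null_prop <- c(0.04, 0.02, stats::runif(max(0L, n_null - 2L), 1e-4, 2e-3))
  prop[null_ids] <- null_prop[seq_along(null_ids)]
  prop[star_ids] <- 0.03 * prop[star_host]
  if (length(star_ids) >= 4L) {             # two star-dominant pairs, picked
    dom <- utils::tail(seq_along(star_ids), 2L)  # low-expression hosts
    prop[star_ids[dom]] <- 4 * prop[star_host[dom]]
  }
  prop[novel_ids] <- 8e-4

  planted_class <- stats::setNames(rep("null", nrow(mult)), rownames(mult))
  planted_class[seq_len(n_planted)] <- eff$class

  truth <- structure(list(
    genome = genome, tracks = tracks, catalog = catalog,
    novel = data.frame(id = novel_ids, seq = novel_mature,
                       star = vapply(novel_hp, `[[`, "", "star"),
                       locus = as.character(novel_loci),
                       stringsAsFactors = FALSE),
    features = features, mirna_prop = prop, mult = mult,
    planted_class = planted_class, libspec = libs, config = config),
    class = "sim_truth")
  truth$expected_class <- expected_phase_truth(truth)
  truth
}

# Does a planted novel hairpin pass the default criteria in its genomic
# context (tag +/- flank window, builtin engine)?
novel_conforms <- function(mature, hp, prec_locus, genome, cfg) {
  str <- as.character(GenomicRanges::strand(prec_locus))
  off <- hp$mature_offset
  if (str == "+") {
    s <- GenomicRanges::start(prec_locus) + off - 1L
    e <- s + nchar(mature) - 1L
  } else {
    e <- GenomicRanges::end(prec_locus) - off + 1L
    s <- e - nchar(mature) + 1L
  }
  tag_locus <- GenomicRanges::GRanges(
    GenomicRanges::seqnames(prec_locus), IRanges::IRanges(s, e), str)
  fl <- extract_flanks(tag_locus, genome, flank = cfg$flank)
  if (substr(fl$seq, fl$tag_start, fl$tag_start + fl$tag_len - 1L) != mature) {
    return(FALSE)
  }
  cand <- hairpin_criteria(fl$seq, fl$tag_start, fl$tag_len, config = cfg)
  cand$accepted
}

#' Expected phase truth from the planted multipliers
#'
#' Applies the same thresholds as the classifier to the *expected* study:
#' expected counts `depth x proportion x multiplier`, expected clean totals
#' summed over every genome-matched read class, floored RPM, log2
#' fold-change, the count test at the (rounded) expected counts, the
#' significance labels and the F/E/N precedence chain.
#'
#' @param truth A `sim_truth` (fields `mirna_prop`, `mult`, `config`).
#' @return Factor of expected classes (`F`/`E`/`N`/`unresolved`) named by
#'   miRNA id.
#' @export
expected_phase_truth <- function(truth) {
  cfg <- truth$config
  mu <- cfg$depth * truth$mirna_prop * truth$mult        # ids x libs
  cont <- sum(cfg$class_share[setdiff(names(cfg$class_share), "unmatched")])
  totals <- cfg$depth * cont + colSums(mu)
  cfgd <- de_config()
  lab <- function(a, b) {
    na <- normalize_rpm(round(mu[, a]), totals[a], cfgd)
    nb <- normalize_rpm(round(mu[, b]), totals[b], cfgd)
    fc <- log2_fold_change(na, nb)
    p <- count_test_pvalue(round(mu[, a]), totals[a], round(mu[, b]), totals[b])
    de_label(fc, p, cfgd) %in% c("*", "**")
  }
  cls <- classify_phase(lab("CWR-V1", "CWR-V2"),
                        lab("CWR-V1", "CWR-F2"),
                        lab("CWR-V2", "CWR-F2"))
  stats::setNames(cls, rownames(truth$mult))
}

#' Simulate the three read libraries
#'
#' Per-feature counts are negative binomial with mean
#' `depth x proportion x multiplier`; known-miRNA reads include templated
#' +/-2-nt isomiRs at the configured rate; contaminant reads are random
#' sub-windows of their loci; background reads come from intergenic space
#' only; a small share of reads matches the genome nowhere.
#'
#' @param truth Output of [build_genome()]. Uses the current RNG stream
#'   (call [simulate_srna_study()] for the seeded end-to-end path).
#' @return List: `reads` (named list of character vectors per library),
#'   `expected` (expected-count matrix, features x libraries).
#' @export
simulate_libraries <- function(truth) {
  cfg <- truth$config
  libs <- truth$libspec$name
  nb <- function(mu) stats::rnbinom(length(mu), mu = mu, size = cfg$dispersion)
  genome_str <- as.character(truth$genome[[1L]])

  vt <- variant_table(truth$catalog)
  mir_ids <- rownames(truth$mult)
  mu_all <- cfg$depth * truth$mirna_prop * truth$mult
  lens <- as.integer(names(cfg$length_profile))

  sample_lengths <- function(n, max_len = NULL) {
    l <- sample(lens, n, replace = TRUE, prob = cfg$length_profile)
    if (!is.null(max_len)) pmin(l, max_len) else l
  }

  cont_classes <- setdiff(names(cfg$class_share),
                          c("background", "unmatched",
                            "exon_sense", "exon_antisense",
                            "intron_sense", "intron_antisense"))
  # intergenic space for background reads
  occ <- GenomicRanges::reduce(c(GenomicRanges::granges(truth$features)),
                               ignore.strand = TRUE)
  gaps <- GenomicRanges::gaps(occ)
  gaps <- gaps[GenomicRanges::strand(gaps) == "*" &
                 GenomicRanges::width(gaps) > 80L]
  gap_s <- GenomicRanges::start(gaps); gap_w <- GenomicRanges::width(gaps)

  reads <- list()
  expected <- matrix(0, nrow = length(mir_ids), ncol = length(libs),
                     dimnames = list(mir_ids, libs))
  for (li in seq_along(libs)) {
    lib <- libs[li]
    out <- character(0)

    # known + novel miRNA reads
    cnt <- nb(mu_all[, lib])
    expected[, lib] <- mu_all[, lib]
    for (i in seq_along(mir_ids)) {
      n <- cnt[i]
      if (n == 0L) next
      id <- mir_ids[i]
      if (id %in% names(truth$catalog$matures)) {
        vars <- vt[vt$mature_id == id, , drop = FALSE]
        exact <- which(vars$off5 == 0L & vars$off3 == 0L)[1L]
        others <- setdiff(seq_len(nrow(vars)), exact)
        if (length(others) && cfg$isomir_rate > 0) {
          w <- 1 / (abs(vars$off5[others]) + abs(vars$off3[others]))
          pr <- c(1 - cfg$isomir_rate, cfg$isomir_rate * w / sum(w))
          pick <- stats::rmultinom(1L, n, pr)[, 1L]
          out <- c(out, rep(vars$seq[c(exact, others)], pick))
        } else {
          out <- c(out, rep(vars$seq[exact], n))
        }
      } else {
        sq <- truth$novel$seq[truth$novel$id == id]
        out <- c(out, rep(sq, n))
      }
    }
    # star reads of half the novel hairpins (low level, truth for
    # star_observed)
    half <- truth$novel[seq_len(ceiling(nrow(truth$novel) / 2L)), ]
    ns <- nb(rep(cfg$depth * 8e-5, nrow(half)))
    out <- c(out, rep(half$star, ns))

    # contaminant classes
    for (cl in cont_classes) {
      loci <- truth$tracks[[cl]]
      mu <- cfg$depth * cfg$class_share[[cl]] / length(loci)
      ncl <- nb(rep(mu, length(loci)))
      for (k in seq_along(loci)) {
        if (ncl[k] == 0L) next
        w <- GenomicRanges::width(loci[k])
        rl <- sample_lengths(ncl[k], max_len = w)
        st <- GenomicRanges::start(loci[k]) +
          vapply(w - rl, function(m) sample.int(m + 1L, 1L) - 1L, 0L)
        sq <- substring(genome_str, st, st + rl - 1L)
        if (as.character(GenomicRanges::strand(loci[k])) == "-") {
          sq <- revcomp(sq)
        }
        out <- c(out, sq)
      }
    }
    # exon/intron sense and antisense reads
    for (cl in c("exon_sense", "exon_antisense",
                 "intron_sense", "intron_antisense")) {
      feat <- if (grepl("^exon", cl)) truth$tracks$exon else truth$tracks$intron
      n <- nb(cfg$depth * cfg$class_share[[cl]])
      if (n == 0L) next
      pick <- sample.int(length(feat), n, replace = TRUE)
      rl <- sample_lengths(n)
      w <- GenomicRanges::width(feat)[pick]
      rl <- pmin(rl, w)
      st <- GenomicRanges::start(feat)[pick] +
        vapply(w - rl, function(m) sample.int(m + 1L, 1L) - 1L, 0L)
      sq <- substring(genome_str, st, st + rl - 1L)
      gstr <- as.character(GenomicRanges::strand(feat))[pick]
      sense <- grepl("sense$", cl) && !grepl("antisense$", cl)
      flip <- if (sense) gstr == "-" else gstr == "+"
      sq[flip] <- revcomp(sq[flip])
      out <- c(out, sq)
    }
    # intergenic background
    nbk <- nb(cfg$depth * cfg$class_share[["background"]])
    if (nbk > 0L) {
      rl <- sample_lengths(nbk)
      gi <- sample.int(length(gap_s), nbk, replace = TRUE,
                       prob = gap_w / sum(gap_w))
      st <- gap_s[gi] + 5L +
        vapply(gap_w[gi] - rl - 10L,
               function(m) sample.int(max(m, 1L), 1L) - 1L, 0L)
      sq <- substring(genome_str, st, st + rl - 1L)
      neg <- stats::runif(nbk) < 0.5
      sq[neg] <- revcomp(sq[neg])
      out <- c(out, sq)
    }
    # genome-unmatched junk
    nj <- nb(cfg$depth * cfg$class_share[["unmatched"]])
    if (nj > 0L) {
      out <- c(out, vapply(sample_lengths(nj), rand_seq, ""))
    }
    reads[[lib]] <- out
  }
  list(reads = reads, expected = expected)
}

#' Simulate a complete synthetic study
#'
#' Seeds the RNG from the configuration, builds the genome and samples the
#' three libraries. Same configuration, same seed: byte-identical output.
#'
#' @param config A [sim_config()].
#' @return List of class `sim_study`: all `sim_truth` fields plus `reads`
#'   and `expected`.
#' @export
simulate_srna_study <- function(config) {
  truth <- build_genome(config)      # seeds the RNG
  sim <- simulate_libraries(truth)
  truth$reads <- sim$reads
  truth$expected <- sim$expected
  class(truth) <- c("sim_study", class(truth))
  truth
}

#' Write study fixtures to disk
#'
#' Emits the genome FASTA, per-class BED/GFF3 tracks, catalog FASTA pair,
#' per-library read FASTA and the truth tables (TSV), all plain text.
#'
#' @param sim A `sim_study` from [simulate_srna_study()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim_fixtures <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  Biostrings::writeXStringSet(sim$genome, file.path(dir, "genome.fa"))
  for (cl in names(sim$tracks)) {
    if (length(sim$tracks[[cl]])) {
      write_gff3(sim$tracks[[cl]], file.path(dir, paste0("track_", cl, ".gff3")))
    }
  }
  mat <- Biostrings::DNAStringSet(sim$catalog$matures)
  Biostrings::writeXStringSet(mat, file.path(dir, "mature.fa"))
  pre <- Biostrings::DNAStringSet(sim$catalog$precursors)
  Biostrings::writeXStringSet(pre, file.path(dir, "hairpin.fa"))
  for (lib in names(sim$reads)) {
    rd <- Biostrings::DNAStringSet(sim$reads[[lib]])
    names(rd) <- paste0("read", seq_along(rd))
    Biostrings::writeXStringSet(rd, file.path(dir, paste0(lib, ".fa")))
  }
  utils::write.table(
    data.frame(id = rownames(sim$mult), planted = sim$planted_class,
               expected = as.character(sim$expected_class), sim$mult,
               check.names = FALSE),
    file.path(dir, "truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
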