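# Novel-miRNA prediction: flank extraction around unannotated tags, hairpin
# folding, plant-miRNA annotation criteria, genomic-context classification
# and multi-locus grouping.

#' Default hairpin acceptance thresholds
#'
#' Duplex criteria follow the community plant-miRNA annotation standard
#' (at most 4 mismatched bases between the mature and its star region, at
#' most a 2-nt asymmetric bulge); the energy floor and precursor length
#' window bracket the values observed for accepted plant precursors.
#' Thresholds are engine-specific; these defaults refer to the builtin
#' folding engine.
#'
#' @param max_mismatch Maximum unpaired mature bases within the duplex.
#' @param max_bulge Maximum asymmetry (nt) of any internal loop/bulge in
#'   the duplex.
#' @param mfe_max Maximum (least negative) folding energy, kcal/mol.
#' @param prec_len Allowed trimmed-precursor length range, nt.
#' @param min_reads Minimum summed read count for a tag to enter discovery.
#' @param flank Flank size (nt) extracted on each side of the tag.
#' @param engine Folding engine, see [fold_rna()].
#' @return A named list of thresholds.
#' @export
hairpin_config <- function(max_mismatch = 4L, max_bulge = 2L, mfe_max = -18,
                           prec_len = c(60L, 380L), min_reads = 5L,
                           flank = 150L, engine = "builtin") {
  list(max_mismatch = max_mismatch, max_bulge = max_bulge, mfe_max = mfe_max,
       prec_len = prec_len, min_reads = min_reads, flank = flank,
       engine = engine)
}

#' Extract the genomic window around a tag locus
#'
#' Returns the tag with `flank` nt of genomic context on each side (clipped
#' at chromosome ends); minus-strand loci return the reverse complement so
#' the tag always reads 5'->3' within the window.
#'
#' @param locus A length-1 `GRanges`.
#' @param genome Named `DNAStringSet`.
#' @param flank Flank size, nt (default 150, giving a ~320-nt window for a
#'   20-nt tag).
#' @return List: `seq` (window sequence), `window` (`GRanges`), `tag_start`
#'   (1-based tag offset within `seq`), `tag_len`.
#' @export
extract_flanks <- function(locus, genome, flank = 150L) {
  stopifnot(methods::is(locus, "GRanges"), length(locus) == 1L)
  chr <- as.character(GenomicRanges::seqnames(locus))
  if (!chr %in% names(genome)) stopf("locus chromosome '%s' not in genome", chr)
  L <- length(genome[[chr]])
  s <- GenomicRanges::start(locus); e <- GenomicRanges::end(locus)
  ws <- max(1L, s - flank); we <- min(L, e + flank)
  seq <- as.character(Biostrings::subseq(genome[[chr]], ws, we))
  minus <- as.character(GenomicRanges::strand(locus)) == "-"
  if (minus) {
    seq <- revcomp(seq)
    tag_start <- we - e + 1L
  } else {
    tag_start <- s - ws + 1L
  }
  list(seq = seq,
       window = GenomicRanges::GRanges(chr, IRanges::IRanges(ws, we),
                                       if (minus) "-" else "+"),
       tag_start = tag_start, tag_len = e - s + 1L)
}

#' Apply hairpin acceptance criteria to a folded window
#'
#' A candidate is accepted iff (a) the tag lies wholly on one arm of a
#' single stem-loop, (b) it pairs against a star region with at most
#' `max_mismatch` unpaired tag bases, (c) no internal loop/bulge in the
#' duplex is asymmetric by more than `max_bulge` nt, (d) the folding energy
#' is at most `mfe_max`, and (e) the trimmed hairpin length falls within
#' `prec_len`. Reason codes record every failed criterion, so acceptance is
#' monotone in the thresholds.
#'
#' @param window_seq Window sequence (from [extract_flanks()]).
#' @param tag_start,tag_len Tag position within the window.
#' @param fold Optional precomputed [fold_rna()] result for the window.
#' @param config Thresholds from [hairpin_config()].
#' @return An object of class `hairpin_candidate`.
#' @export
hairpin_criteria <- function(window_seq, tag_start, tag_len, fold = NULL,
                             config = hairpin_config()) {
  if (is.null(fold)) fold <- fold_rna(window_seq, engine = config$engine)
  partner <- fold$partner
  n <- nchar(window_seq)
  ts <- tag_start; te <- tag_start + tag_len - 1L
  if (ts < 1L || te > n) stopf("tag does not lie within the window")
  reasons <- character(0)

  p <- partner[ts:te]
  paired <- p > 0L
  mismatches <- sum(!paired)
  partners <- p[paired]

  if (!any(paired) || any(partners >= ts & partners <= te)) {
    # tag folds on itself / spans the terminal loop, or pairs nowhere
    reasons <- c(reasons, "arm")
  } else if (!(all(partners < ts) || all(partners > te))) {
    reasons <- c(reasons, "arm")
  } else if (any(diff(partners) >= 0L)) {
    # partners must descend as the tag advances: one nested helix
    reasons <- c(reasons, "multistem")
  }

  bulge_asym <- 0L
  if (!length(reasons) && sum(paired) >= 2L) {
    pos <- which(paired)
    gap_tag <- diff(pos) - 1L
    gap_star <- -diff(partners) - 1L
    bulge_asym <- max(abs(gap_tag - gap_star))
    if (bulge_asym > config$max_bulge) reasons <- c(reasons, "bulge")
  }
  if (mismatches > config$max_mismatch) reasons <- c(reasons, "mismatch")
  if (fold$mfe > config$mfe_max) reasons <- c(reasons, "mfe")

  prec <- c(NA_integer_, NA_integer_)
  star_seq <- NA_character_
  mature_arm <- NA_character_
  if (any(paired) && !("arm" %in% reasons)) {
    a <- min(ts, min(partners)); b <- max(te, max(partners))
    while (a > 1L && b < n && partner[a - 1L] == b + 1L) {
      a <- a - 1L; b <- b + 1L
    }
    prec <- c(a, b)
    star_seq <- substr(window_seq, min(partners), max(partners))
    mature_arm <- if (all(partners > te)) "5p" else "3p"
    plen <- b - a + 1L
    if (plen < config$prec_len[1L] || plen > config$prec_len[2L]) {
      reasons <- c(reasons, "length")
    }
  }
  structure(list(sequence = window_seq, structure = fold$structure,
                 mfe = fold$mfe, engine = fold$engine,
                 tag_start = ts, tag_len = tag_len,
                 mature_arm = mature_arm, star_seq = star_seq,
                 star_span = if (any(paired)) c(min(partners), max(partners))
                             else c(NA_integer_, NA_integer_),
                 duplex_mismatches = mismatches,
                 bulge_asymmetry = bulge_asym,
                 precursor_span = prec,
                 accepted = length(reasons) == 0L,
                 reasons = reasons),
            class = "hairpin_candidate")
}

#' @export
print.hairpin_candidate <- function(x, ...) {
  cat(sprintf("hairpin_candidate: %s (mfe %.1f, %d mismatches%s)\n",
              if (x$accepted) "ACCEPTED" else "rejected",
              x$mfe, x$duplex_mismatches,
              if (x$accepted) "" else paste0("; ", paste(x$reasons,
                                                         collapse = ","))))
  invisible(x)
}

#' Classify the genomic context of loci
#'
#' Precedence: UTR > intron-exon junction > exon > intron > intergenic, so
#' every locus gets exactly one label.
#'
#' @param loci A `GRanges`.
#' @param tracks Named list with optional `utr`, `exon`, `intron` `GRanges`.
#' @return Character vector of context labels, one per locus.
#' @export
classify_context <- function(loci, tracks) {
  hits <- function(trk) {
    if (is.null(trk)) return(rep(FALSE, length(loci)))
    IRanges::overlapsAny(loci, trk, ignore.strand = TRUE)
  }
  in_utr <- hits(tracks$utr)
  in_ex <- hits(tracks$exon)
  in_in <- hits(tracks$intron)
  out <- rep("intergenic", length(loci))
  out[in_in] <- "intron"
  out[in_ex] <- "exon"
  out[in_ex & in_in] <- "intron-exon junction"
  out[in_utr] <- "UTR"
  out
}

#' Merge accepted candidates that share a mature sequence
#'
#' Candidates with an identical mature (tag) sequence merge into one novel
#' miRNA carrying all loci; ids are assigned `oru-miR1..n` in discovery
#' order. The merged (mature, loci-set) content is independent of input
#' order.
#'
#' @param candidates data.frame with at least `seq` (mature sequence) and
#'   `locus` (character locus key) columns, one row per accepted
#'   (tag, locus) pair; extra columns are carried from the first row.
#' @param prefix Id prefix (default `"oru-miR"`).
#' @return data.frame, one row per novel miRNA: `id`, `seq`, `n_loci`,
#'   `loci` (comma-joined), plus carried columns.
#' @export
group_multilocus <- function(candidates, prefix = "oru-miR") {
  if (nrow(candidates) == 0L) {
    return(data.frame(id = character(0), seq = character(0),
                      n_loci = integer(0), loci = character(0)))
  }
  first <- !duplicated(candidates$seq)
  uniq <- candidates[first, setdiff(names(candidates), "locus"), drop = FALSE]
  loci <- vapply(uniq$seq, function(s) {
    paste(sort(unique(candidates$locus[candidates$seq == s])), collapse = ",")
  }, "")
  out <- data.frame(id = paste0(prefix, seq_len(nrow(uniq))),
                    seq = uniq$seq,
                    n_loci = lengths(strsplit(loci, ",", fixed = TRUE)),
                    loci = unname(loci), stringsAsFactors = FALSE)
  extra <- setdiff(names(uniq), c("seq"))
  for (cn in extra) out[[cn]] <- uniq[[cn]]
  rownames(out) <- NULL
  out
}

#' Discover novel miRNA candidates among unannotated tags
#'
#' For every unannotated tag with at least `min_reads` summed reads, each
#' genomic locus is expanded by `flank` nt, folded, and passed through the
#' hairpin criteria. Accepted (tag, locus) pairs are grouped into novel
#' miRNAs; the full candidate table (including rejections with reason
#' codes) is retained for reporting.
#'
#' @param tags An `srna_tags` object after [match_genome()].
#' @param annot Annotation records from [assign_categories()].
#' @param genome Named `DNAStringSet`.
#' @param tracks Optional track list for context classification (`utr`,
#'   `exon`, `intron`).
#' @param config Thresholds from [hairpin_config()].
#' @return List: `novel` (grouped accepted miRNAs with context and
#'   star-observed flag), `candidates` (per-locus verdict table).
#' @export
discover_novel <- function(tags, annot, genome, tracks = NULL,
                           config = hairpin_config()) {
  stopifnot(inherits(tags, "srna_tags"))
  unann <- annot$seq[annot$category == "unannotated"]
  idx <- which(tags$seq %in% unann & rowSums(tags$counts) >= config$min_reads)
  rows <- list(); acc_loci <- list()
  for (i in idx) {
    loci <- tag_loci(tags, i)
    for (k in seq_along(loci)) {
      fl <- extract_flanks(loci[k], genome, flank = config$flank)
      cand <- hairpin_criteria(fl$seq, fl$tag_start, fl$tag_len,
                               config = config)
      key <- as.character(loci[k])
      rows[[length(rows) + 1L]] <- data.frame(
        seq = tags$seq[i], locus = key, reads = sum(tags$counts[i, ]),
        mfe = cand$mfe, mature_arm = cand$mature_arm %||% NA_character_,
        accepted = cand$accepted,
        reasons = paste(cand$reasons, collapse = ";"),
        stringsAsFactors = FALSE)
      if (cand$accepted) {
        star <- star_genomic_span(cand, fl)
        acc_loci[[length(acc_loci) + 1L]] <-
          list(seq = tags$seq[i], locus = key, gr = loci[k], star = star)
      }
    }
  }
  candidates <- if (length(rows)) do.call(rbind, rows) else
    data.frame(seq = character(0), locus = character(0), reads = numeric(0),
               mfe = numeric(0), mature_arm = character(0),
               accepted = logical(0), reasons = character(0))
  acc <- candidates[candidates$accepted, , drop = FALSE]
  novel <- group_multilocus(acc)
  if (nrow(novel)) {
    gr_all <- do.call(c, lapply(acc_loci, `[[`, "gr"))
    seq_all <- vapply(acc_loci, `[[`, "", "seq")
    if (!is.null(tracks)) {
      ctx <- classify_context(gr_all, tracks)
      novel$context <- vapply(novel$seq, function(s) {
        paste(unique(ctx[seq_all == s]), collapse = ",")
      }, "")
    }
    stars <- do.call(c, lapply(acc_loci, `[[`, "star"))
    novel$star_observed <- vapply(novel$seq, function(s) {
      any(star_has_tag(stars[seq_all == s], tags))
    }, TRUE)
  }
  list(novel = novel, candidates = candidates)
}

# Genomic interval of the predicted star region of an accepted candidate.
star_genomic_span <- function(cand, fl) {
  w <- fl$window
  a <- cand$star_span[1L]; b <- cand$star_span[2L]
  if (as.character(GenomicRanges::strand(w)) == "+") {
    st <- GenomicRanges::start(w) + a - 1L
    en <- GenomicRanges::start(w) + b - 1L
  } else {
    en <- GenomicRanges::end(w) - a + 1L
    st <- GenomicRanges::end(w) - b + 1L
  }
  GenomicRanges::GRanges(GenomicRanges::seqnames(w),
                         IRanges::IRanges(st, en),
                         GenomicRanges::strand(w))
}

# Is any sequenced tag covering >= 75% of its own length inside a star span?
star_has_tag <- function(stars, tags) {
  if (length(stars) == 0L) return(FALSE)
  loci <- hits_granges(tags)
  if (length(loci) == 0L) return(FALSE)
  ov <- GenomicRanges::findOverlaps(loci, stars, ignore.strand = TRUE)
  if (length(ov) == 0L) return(FALSE)
  qi <- S4Vectors::queryHits(ov)
  inter <- GenomicRanges::pintersect(loci[qi],
                                     stars[S4Vectors::subjectHits(ov)],
                                     ignore.strand = TRUE)
  any(GenomicRanges::width(inter) >= 0.75 * GenomicRanges::width(loci[qi]))
}
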