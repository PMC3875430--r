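# Plant miRNA target prediction: seed-weighted complementarity penalty
# ("expectation") in the miRU/psRNATarget tradition, transcriptome scanning,
# flowering-gene annotation and 5'-RACE cleavage-site mapping.

#' Target-scoring constants
#'
#' Penalties: mismatch 1.0, G:U wobble 0.5, single-nt gap 2.0, all doubled
#' when they fall at miRNA positions 2-13 (the seed-proximal region that
#' dominates plant target recognition). Lower expectation = better site;
#' sites above `cutoff` are not reported. At most one internal gap is
#' allowed per site.
#'
#' @param mismatch,wobble,gap Penalty constants.
#' @param seed Seed-proximal miRNA position range (inclusive).
#' @param seed_mult Penalty multiplier inside `seed`.
#' @param cutoff Maximum reported expectation.
#' @return Named list of constants.
#' @export
target_config <- function(mismatch = 1, wobble = 0.5, gap = 2,
                          seed = c(2L, 13L), seed_mult = 2, cutoff = 3) {
  list(mismatch = mismatch, wobble = wobble, gap = gap, seed = seed,
       seed_mult = seed_mult, cutoff = cutoff)
}

# Penalty for pairing miRNA base m against target base t (DNA alphabet;
# ambiguous bases count as mismatches). G:U wobble = miRNA G on target T,
# or miRNA T on target G.
pair_penalty <- function(m, t, config) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  if (!m %in% names(comp) || !t %in% c("A", "C", "G", "T")) {
    return(config$mismatch)
  }
  if (comp[[m]] == t) return(0)
  if ((m == "G" && t == "T") || (m == "T" && t == "G")) return(config$wobble)
  config$mismatch
}

pos_weight <- function(i, config) {
  ifelse(i >= config$seed[1L] & i <= config$seed[2L], config$seed_mult, 1)
}

#' Score one miRNA against one candidate target site
#'
#' The site is a transcript window read 5'->3'; the miRNA binds antiparallel,
#' so miRNA position 1 (its 5' end) pairs the window's last base. Window
#' lengths of miRNA length +/- 1 are handled with a single internal gap
#' (terminal gaps are not considered gaps -- they are shorter sites).
#'
#' @param mirna miRNA sequence (5'->3'; U or T).
#' @param site Transcript window (5'->3').
#' @param config Constants from [target_config()].
#' @return List: `expectation`, `alignment` (3-line character vector:
#'   target 5'->3', pairing marks `|`=match `o`=wobble, miRNA 3'->5'),
#'   `gap` (`"none"`, `"mirna"`, or `"target"`).
#' @export
score_site <- function(mirna, site, config = target_config()) {
  m <- strsplit(canonicalize_dna(mirna), "")[[1L]]
  t <- strsplit(canonicalize_dna(site), "")[[1L]]
  L <- length(m); W <- length(t)
  if (abs(W - L) > 1L) stopf("site length must be within 1 nt of the miRNA")

  best <- NULL
  consider <- function(cand) {
    if (is.null(best) || cand$expectation < best$expectation) best <<- cand
  }
  if (W == L) {
    e <- 0
    marks <- character(L)
    for (i in seq_len(L)) {
      p <- pair_penalty(m[i], t[W - i + 1L], config)
      e <- e + p * pos_weight(i, config)
      marks[W - i + 1L] <- if (p == 0) "|" else if (p == config$wobble) "o" else " "
    }
    consider(list(expectation = e, gap = "none",
                  alignment = c(paste(t, collapse = ""),
                                paste(marks, collapse = ""),
                                paste(rev(m), collapse = ""))))
  } else if (W == L - 1L) {
    for (g in seq(2L, L - 1L)) {  # miRNA base g unpaired (gap in target)
      e <- config$gap * pos_weight(g, config)
      top <- bot <- marks <- character(W + 1L)
      for (i in seq_len(L)) {
        if (i == g) next
        w <- if (i < g) W - i + 1L else W - i + 2L
        p <- pair_penalty(m[i], t[w], config)
        e <- e + p * pos_weight(i, config)
      }
      # columns right-to-left in miRNA order
      cols <- integer(L)
      for (i in seq_len(L)) cols[i] <- L - i + 1L
      for (i in seq_len(L)) {
        bot[cols[i]] <- m[i]
        if (i == g) { top[cols[i]] <- "-"; marks[cols[i]] <- " " }
        else {
          w <- if (i < g) W - i + 1L else W - i + 2L
          top[cols[i]] <- t[w]
          p <- pair_penalty(m[i], t[w], config)
          marks[cols[i]] <- if (p == 0) "|" else if (p == config$wobble) "o" else " "
        }
      }
      consider(list(expectation = e, gap = "target",
                    alignment = c(paste(top[seq_len(L)], collapse = ""),
                                  paste(marks[seq_len(L)], collapse = ""),
                                  paste(rev(m), collapse = ""))))
    }
  } else {  # W == L + 1: one bulged target base between miRNA g and g+1
    for (g in seq_len(L - 1L)) {
      e <- config$gap * pos_weight(g + 1L, config)
      for (i in seq_len(L)) {
        w <- if (i <= g) W - i + 1L else W - i
        e <- e + pair_penalty(m[i], t[w], config) * pos_weight(i, config)
      }
      ncol_ <- W
      top <- marks <- bot <- character(ncol_)
      for (w in seq_len(W)) top[w] <- t[w]
      for (i in seq_len(L)) {
        w <- if (i <= g) W - i + 1L else W - i
        bot[w] <- m[i]
        p <- pair_penalty(m[i], t[w], config)
        marks[w] <- if (p == 0) "|" else if (p == config$wobble) "o" else " "
      }
      bulge_col <- W - g  # the unpaired target base
      bot[bulge_col] <- "-"; marks[bulge_col] <- " "
      consider(list(expectation = e, gap = "mirna",
                    alignment = c(paste(top, collapse = ""),
                                  paste(marks, collapse = ""),
                                  paste(bot, collapse = ""))))
    }
  }
  best
}

#' Scan a transcriptome for miRNA target sites
#'
#' Every transcript window whose expectation is at or below the cutoff is
#' reported (a transcript may be hit by several miRNAs and a miRNA may hit
#' several transcripts). Gapless windows and windows one nt shorter/longer
#' (one internal gap) are scanned. The scan is a vectorized computation;
#' it agrees with exhaustive window-by-window scoring by construction and
#' by property test.
#'
#' @param mirnas Named character vector of miRNA sequences.
#' @param transcripts Named character vector or `DNAStringSet`.
#' @param config Constants from [target_config()].
#' @param dedupe Collapse overlapping windows of one miRNA on one
#'   transcript to the best-scoring window (default). A strong site is
#'   flanked by shifted/gapped windows that can also clear the cutoff;
#'   with `dedupe = TRUE` each site region is reported once. Set
#'   `dedupe = FALSE` for the raw all-windows enumeration.
#' @return data.frame: `mirna_id`, `transcript_id`, `start`, `end`
#'   (1-based inclusive site interval), `expectation`, `gap`.
#' @export
scan_targets <- function(mirnas, transcripts, config = target_config(),
                         dedupe = TRUE) {
  tr <- stats::setNames(canonicalize_dna(transcripts), names(transcripts))
  out <- list()
  for (mid in names(mirnas)) {
    m <- canonicalize_dna(mirnas[[mid]])
    for (tid in names(tr)) {
      hits <- scan_one(m, tr[[tid]], config)
      if (dedupe && nrow(hits) > 1L) hits <- dedupe_hits(hits)
      if (nrow(hits)) {
        hits$mirna_id <- mid; hits$transcript_id <- tid
        out[[length(out) + 1L]] <- hits
      }
    }
  }
  if (!length(out)) {
    return(data.frame(mirna_id = character(0), transcript_id = character(0),
                      start = integer(0), end = integer(0),
                      expectation = numeric(0), gap = character(0)))
  }
  res <- do.call(rbind, out)
  res[c("mirna_id", "transcript_id", "start", "end", "expectation", "gap")]
}

# Vectorized scan of one miRNA over one transcript.
scan_one <- function(m, tseq, config) {
  mb <- strsplit(m, "")[[1L]]
  L <- length(mb)
  tcode <- match(strsplit(tseq, "")[[1L]], c("A", "C", "G", "T"))
  tcode[is.na(tcode)] <- 5L
  n <- length(tcode)
  # penalty of miRNA base (row) against target code (col; 5 = ambiguous)
  PEN <- matrix(config$mismatch, nrow = 4L, ncol = 5L,
                dimnames = list(c("A", "C", "G", "T"), NULL))
  PEN["A", 4L] <- 0; PEN["T", 1L] <- 0; PEN["C", 3L] <- 0; PEN["G", 2L] <- 0
  PEN["G", 4L] <- config$wobble; PEN["T", 3L] <- config$wobble
  wt <- pos_weight(seq_len(L), config)
  pen_at <- function(i, abs_idx) wt[i] * PEN[mb[i], tcode[abs_idx]]

  rows <- list()
  add <- function(s, W, e, gap) {
    keep <- which(e <= config$cutoff)
    if (length(keep)) {
      rows[[length(rows) + 1L]] <<- data.frame(
        start = s[keep], end = s[keep] + W - 1L,
        expectation = e[keep], gap = gap, stringsAsFactors = FALSE)
    }
  }

  if (n >= L) {                       # gapless
    s <- seq_len(n - L + 1L)
    e <- numeric(length(s))
    for (i in seq_len(L)) e <- e + pen_at(i, s + (L - i))
    add(s, L, e, "none")
  }
  if (n >= L - 1L && L >= 3L) {       # miRNA base g unpaired (window L-1)
    W <- L - 1L
    s <- seq_len(n - W + 1L)
    A <- B <- matrix(0, nrow = L, ncol = length(s))
    for (i in seq_len(L - 1L)) A[i, ] <- pen_at(i, s + (W - i))
    for (i in seq(2L, L)) B[i, ] <- pen_at(i, s + (W - i + 1L))
    cumA <- apply(A, 2L, cumsum)
    revB <- apply(B[L:1, , drop = FALSE], 2L, cumsum)[L:1, , drop = FALSE]
    best <- rep(Inf, length(s))
    for (g in seq(2L, L - 1L)) {
      e <- cumA[g - 1L, ] + config$gap * wt[g] + revB[g + 1L, ]
      best <- pmin(best, e)
    }
    add(s, W, best, "target")
  }
  if (n >= L + 1L) {                  # bulged target base (window L+1)
    W <- L + 1L
    s <- seq_len(n - W + 1L)
    C <- D <- matrix(0, nrow = L, ncol = length(s))
    for (i in seq_len(L)) C[i, ] <- pen_at(i, s + (W - i))
    for (i in seq_len(L)) D[i, ] <- pen_at(i, s + (W - i - 1L))
    cumC <- apply(C, 2L, cumsum)
    revD <- apply(D[L:1, , drop = FALSE], 2L, cumsum)[L:1, , drop = FALSE]
    best <- rep(Inf, length(s))
    for (g in seq_len(L - 1L)) {
      e <- cumC[g, ] + config$gap * wt[g + 1L] + revD[g + 1L, ]
      best <- pmin(best, e)
    }
    add(s, W, best, "mirna")
  }
  if (!length(rows)) {
    return(data.frame(start = integer(0), end = integer(0),
                      expectation = numeric(0), gap = character(0)))
  }
  do.call(rbind, rows)
}

# Greedy best-first collapse of overlapping windows (gapless preferred on
# score ties, then leftmost).
dedupe_hits <- function(hits) {
  ord <- order(hits$expectation, hits$gap != "none", hits$start)
  hits <- hits[ord, , drop = FALSE]
  keep <- logical(nrow(hits))
  occ_s <- integer(0); occ_e <- integer(0)
  for (i in seq_len(nrow(hits))) {
    if (!any(hits$start[i] <= occ_e & hits$end[i] >= occ_s)) {
      keep[i] <- TRUE
      occ_s <- c(occ_s, hits$start[i]); occ_e <- c(occ_e, hits$end[i])
    }
  }
  out <- hits[keep, , drop = FALSE]
  out[order(out$start), , drop = FALSE]
}

#' Mean number of targets per targeted miRNA
#'
#' @param hits Hit table from [scan_targets()] (or any data.frame with a
#'   `mirna_id` column, one row per hit).
#' @return Mean hits over miRNAs with at least one hit, rounded to one
#'   decimal (the conventional reporting precision).
#' @export
average_targets_per_mirna <- function(hits) {
  if (nrow(hits) == 0L) stopf("no miRNA has any target hit")
  round(nrow(hits) / length(unique(hits$mirna_id)), 1L)
}

#' Flag target hits on flowering-related genes
#'
#' A local annotation join: a hit is flowering-flagged when its transcript
#' id appears in the gene list, or its description matches one of the
#' keyword patterns (case-insensitive). A miRNA is flowering-related iff at
#' least one of its hits is flagged.
#'
#' @param hits Hit table from [scan_targets()].
#' @param flowering data.frame with columns `type` (`"id"` or `"keyword"`)
#'   and `value`, as read from a flowering-gene TSV.
#' @param descriptions Optional named character vector of transcript
#'   descriptions (names = transcript ids) for keyword matching.
#' @return List: `hits` (input plus logical `flowering_flag`),
#'   `flowering_mirnas` (sorted ids), `n_flowering`.
#' @export
annotate_flowering <- function(hits, flowering, descriptions = NULL) {
  ids <- flowering$value[flowering$type == "id"]
  kws <- flowering$value[flowering$type == "keyword"]
  flag <- hits$transcript_id %in% ids
  if (length(kws) && !is.null(descriptions)) {
    desc <- descriptions[hits$transcript_id]
    desc[is.na(desc)] <- ""
    pat <- paste(kws, collapse = "|")
    flag <- flag | grepl(pat, desc, ignore.case = TRUE)
  }
  hits$flowering_flag <- flag
  fm <- sort(unique(hits$mirna_id[flag]))
  list(hits = hits, flowering_mirnas = fm, n_flowering = length(fm))
}

#' Read a flowering-gene annotation list
#'
#' @param path TSV with columns `type` (`id`/`keyword`) and `value`. The
#'   packaged example list lives at
#'   `system.file("extdata", "flowering_genes.tsv", package = "mirphase")`.
#' @return data.frame with `type` and `value`.
#' @export
read_flowering_genes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  if (!all(c("type", "value") %in% names(df))) {
    stopf("flowering gene list needs 'type' and 'value' columns")
  }
  df
}

#' Map 5'-RACE clone ends onto a target site
#'
#' Each clone 5' end (transcript coordinate) is re-expressed as the bond
#' between miRNA nucleotides i and i+1 counting from the miRNA 5' end
#' (which pairs the 3' end of the site). Clone ends more than 5 nt outside
#' the site are reported off-site. The modal site is the position with the
#' highest clone count (first wins on ties).
#'
#' @param hit One target hit: a list or single-row data.frame with
#'   `transcript_id`, `start`, `end`.
#' @param clones data.frame of clone ends: `transcript_id`, `position`
#'   (1-based transcript coordinate of the clone 5' end), `count` (> 0).
#' @return An object of class `cleavage_profile`: data.frame of on-site
#'   positions (`position`, `count`, `mirna_bond`, `label`), `off_site`
#'   rows, and `modal` (label of the modal site, `NA` if empty).
#' @export
map_cleavage_sites <- function(hit, clones) {
  if (any(clones$count <= 0)) stopf("clone counts must be positive")
  cl <- clones[clones$transcript_id == hit$transcript_id, , drop = FALSE]
  s <- hit$start; e <- hit$end
  on <- cl$position >= s - 5L & cl$position <= e + 5L
  onsite <- cl[on, , drop = FALSE]
  bond <- e - onsite$position + 1L
  prof <- data.frame(position = onsite$position, count = onsite$count,
                     mirna_bond = bond,
                     label = sprintf("%d-%d", bond, bond + 1L),
                     stringsAsFactors = FALSE)
  prof <- prof[order(-prof$count, prof$position), , drop = FALSE]
  rownames(prof) <- NULL
  structure(list(sites = prof, off_site = cl[!on, , drop = FALSE],
                 modal = if (nrow(prof)) prof$label[1L] else NA_character_),
            class = "cleavage_profile")
}

#' @export
print.cleavage_profile <- function(x, ...) {
  cat(sprintf("cleavage_profile: %d on-site position(s), modal %s\n",
              nrow(x$sites), x$modal %||% "none"))
  if (nrow(x$sites)) print(x$sites)
  invisible(x)
}
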