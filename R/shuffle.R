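# Dinucleotide-preserving sequence shuffle (Altschul-Erickson Euler-path
# algorithm), used to build the null distribution for hairpin calling.

#' Shuffle a sequence preserving its dinucleotide composition
#'
#' Implements the Euler-path shuffle: the sequence is viewed as a walk on
#' the 4-letter multigraph of its dinucleotides; a uniformly random Eulerian
#' walk with the same start and end letters is returned, so mono- and
#' dinucleotide counts are conserved exactly. Uses the R RNG (seed with
#' [set.seed()] for reproducibility).
#'
#' @param seq A nucleotide string (length >= 2).
#' @return A shuffled string with identical dinucleotide composition.
#' @export
dinucleotide_shuffle <- function(seq) {
  s <- strsplit(canonicalize_dna(seq), "")[[1L]]
  n <- length(s)
  if (n < 3L) return(paste(s, collapse = ""))
  verts <- unique(s)
  from <- s[-n]; to <- s[-1L]
  last_v <- s[n]
  out_edges <- split(to, factor(from, levels = verts))

  repeat {
    # pick a candidate last out-edge for every vertex except the final one
    last_edge <- stats::setNames(rep(NA_character_, length(verts)), verts)
    for (v in verts) {
      if (v == last_v) next
      es <- out_edges[[v]]
      if (length(es) == 0L) next
      last_edge[v] <- es[sample.int(length(es), 1L)]
    }
    # the chosen last edges must lead every vertex to the final vertex
    ok <- TRUE
    for (v in verts) {
      if (v == last_v || is.na(last_edge[v])) next
      seen <- character(0); cur <- v
      while (cur != last_v) {
        if (cur %in% seen || is.na(last_edge[cur])) { ok <- FALSE; break }
        seen <- c(seen, cur)
        cur <- last_edge[cur]
      }
      if (!ok) break
    }
    if (ok) break
  }

  walk_edges <- lapply(verts, function(v) {
    es <- out_edges[[v]]
    if (v != last_v && !is.na(last_edge[v])) {
      # remove one copy of the reserved last edge, shuffle the rest
      drop <- match(last_edge[v], es)
      rest <- es[-drop]
      c(rest[sample.int(length(rest))], last_edge[v])
    } else {
      es[sample.int(length(es))]
    }
  })
  names(walk_edges) <- verts
  ptr <- stats::setNames(rep(1L, length(verts)), verts)
  res <- character(n)
  res[1L] <- s[1L]
  cur <- s[1L]
  for (i in seq(2L, n)) {
    nxt <- walk_edges[[cur]][ptr[cur]]
    ptr[cur] <- ptr[cur] + 1L
    res[i] <- nxt
    cur <- nxt
  }
  paste(res, collapse = "")
}
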