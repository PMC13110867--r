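#' Mutation events on an edge
#'
#' Computes `(h_parent XOR h_child) AND m_omega`, where `m_omega` masks
#' markers outside the interval set `omega` (and outside the edge's own
#' ancestral material) to zero, and returns the indices of the set bits:
#' the markers that mutate on the edge within `omega`. The parent of a
#' recombination vertex compares against the child's haplotype, which is
#' identical by construction, so such edges never carry mutations.
#'
#' @param g a genealogy.
#' @param e an active edge id.
#' @param omega an [iset()]; defaults to the whole sequence.
#' @return Sorted 1-based marker indices.
#' @export
edge_mutations <- function(g, e, omega = NULL) {
  pos <- g$sample$positions
  win <- g$e_anc[[e]]
  if (!is.null(omega)) win <- iset_intersect(win, omega)
  m <- interval_mask(pos, win)
  d <- masked_xor(g$hap[[g$e_parent[e]]], g$hap[[g$e_child[e]]], m)
  which(as_bits(d) == 1L)
}

#' Find the next inconsistent marker (minimum-mutation-number scan)
#'
#' Scans markers left to right from `from_marker` for the first whose
#' marginal tree carries two or more mutation edges, returning that marker
#' together with its full set of mutation edges `M`. Markers are processed
#' in chunks (default 8: one packed byte, so a whole chunk of each
#' parent/child haplotype pair is XORed and masked in single bitwise
#' integer operations across all edges at once) and edges are traversed
#' bottom-up by child latitude; an edge whose child haplotype is all-wild
#' on the chunk's live markers is skipped, since 0 is absorbing for the
#' GF(2) product and no mutation can occur there. The result never depends
#' on the chunk width.
#'
#' @param g a genealogy.
#' @param from_marker 1-based marker index to start from.
#' @param omega optional [iset()] restricting the scan window.
#' @param chunk chunk width in markers; default
#'   `getOption("sarg.chunk", 8L)`.
#' @return `NULL` when every marker at or right of the cursor is
#'   consistent; otherwise a list of class `mutation_scan` with
#'   `marker_index` (1-based), `marker_position` and `mutation_edges`
#'   (edge ids sorted by child vertex).
#' @export
next_inconsistent <- function(g, from_marker = 1L, omega = NULL,
                              chunk = getOption("sarg.chunk", 8L)) {
  s <- g$sample$s
  if (from_marker < 1L || from_marker > s)
    stop("from_marker outside 1..", s)
  pos <- g$sample$positions
  es <- active_edges(g)
  es <- es[order(g$lat[g$e_child[es]])]      # bottom-up traversal order
  byte_path <- identical(as.integer(chunk), 8L)
  lo <- if (byte_path) ((from_marker - 1L) %/% 8L) * 8L + 1L else from_marker
  while (lo <= s) {
    hi <- min(s, lo + chunk - 1L)
    idx <- lo:hi
    live <- idx >= from_marker
    if (!is.null(omega)) live <- live & iset_contains(omega, pos[idx])
    if (any(live)) {
      res <- if (byte_path) scan_chunk_byte(g, es, lo, idx, live)
      else scan_chunk_scalar(g, es, idx, live)
      if (!is.null(res)) return(res)
    }
    lo <- hi + 1L
  }
  NULL
}

# fast path: the chunk is one byte of the packed haplotypes, so the
# per-edge XOR/AND acts on whole bytes (vectorized over edges)
scan_chunk_byte <- function(g, es, lo, idx, live) {
  pos <- g$sample$positions
  byte <- (lo - 1L) %/% 8L + 1L
  w <- length(idx)
  vbyte <- vapply(seq_along(g$lat),
                  function(v) as.integer(unclass(g$hap[[v]])[byte]), integer(1))
  pow <- bitwShiftL(1L, 0:(w - 1L))
  memb <- vapply(es, function(e) {
    m <- iset_contains(g$e_anc[[e]], pos[idx]) & live
    if (any(m)) sum(pow[m]) else 0L
  }, integer(1))
  cb <- vbyte[g$e_child[es]]
  pb <- vbyte[g$e_parent[es]]
  diff <- bitwAnd(bitwXor(pb, cb), memb)
  diff[bitwAnd(cb, memb) == 0L] <- 0L       # absorbing-zero early termination
  if (all(diff == 0L)) return(NULL)
  for (j in seq_len(w)) {
    if (!live[j]) next
    hit <- bitwAnd(diff, pow[j]) != 0L
    if (sum(hit) >= 2L) {
      ev <- es[hit]
      ev <- ev[order(g$e_child[ev])]
      return(structure(list(marker_index = idx[j],
                            marker_position = pos[idx[j]],
                            mutation_edges = ev),
                       class = "mutation_scan"))
    }
  }
  NULL
}

# reference path for arbitrary chunk widths (bit-by-bit)
scan_chunk_scalar <- function(g, es, idx, live) {
  pos <- g$sample$positions
  counts <- integer(length(idx))
  hits <- vector("list", length(idx))
  for (e in es) {
    memb <- iset_contains(g$e_anc[[e]], pos[idx]) & live
    if (!any(memb)) next
    cb <- vapply(idx, function(k) vertex_bit(g, g$e_child[e], k), integer(1))
    if (all(cb[memb] == 0L)) next            # absorbing-zero early termination
    pb <- vapply(idx, function(k) vertex_bit(g, g$e_parent[e], k), integer(1))
    for (j in which((cb != pb) & memb)) {
      counts[j] <- counts[j] + 1L
      hits[[j]] <- c(hits[[j]], e)
    }
  }
  bad <- which(counts >= 2L)
  if (length(bad) == 0L) return(NULL)
  j <- bad[1L]
  ev <- hits[[j]]
  ev <- ev[order(g$e_child[ev])]
  structure(list(marker_index = idx[j],
                 marker_position = pos[idx[j]],
                 mutation_edges = ev),
            class = "mutation_scan")
}

#' @export
print.mutation_scan <- function(x, ...) {
  cat("<mutation_scan> marker ", x$marker_index, " at ",
      format(x$marker_position), " bp: ", length(x$mutation_edges),
      " mutation edges\n", sep = "")
  invisible(x)
}
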