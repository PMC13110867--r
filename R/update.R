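#' Hash of an edge state
#'
#' 64-bit NH-family universal hash of a (haplotype, ancestral interval set)
#' pair, used to detect unchanged states during upstream propagation. The
#' key stream is drawn once per genealogy from the run's RNG (so any
#' collision would be reproducible from the recorded seed) and extended
#' lazily as longer messages appear. Equal pairs always hash equally;
#' distinct pairs collide with probability at most `2^-64`.
#'
#' @param g a genealogy (holds the key stream).
#' @param hap a [bitseq()].
#' @param anc an [iset()].
#' @return An integer vector of length 2 (the two 32-bit halves).
#' @export
state_hash <- function(g, hap, anc) {
  nb <- length(unclass(hap))
  nw <- 2L + (nb + 3L) %/% 4L + 2L * (length(unclass(anc)) %/% 2L) * 2L
  nw <- nw + nw %% 2L
  if (length(g$hashkey) < nw) {
    extra <- nw - length(g$hashkey) + 64L
    g$hashkey <- c(g$hashkey,
                   as.integer(sample.int(.Machine$integer.max, extra,
                                         replace = TRUE) -
                                sample.int(.Machine$integer.max, extra,
                                           replace = TRUE)))
  }
  .nh_hash64(unclass(hap), as.numeric(unclass(anc)), g$hashkey)
}

# state flowing along an edge: the child vertex's haplotype and the edge's
# ancestral interval set
edge_state_hash <- function(g, e) {
  state_hash(g, g$hap[[g$e_child[e]]], g$e_anc[[e]])
}

#' Propagate an event's effects upstream
#'
#' After a recombination-and-recoalescence or mask edit, the haplotypes
#' (GF(2) AND of children, masked by ancestrality) and ancestral interval
#' sets (recombination mask intersected with the union of the child edges'
#' sets) of everything upstream of the modified edges must be recomputed.
#' Vertices are processed children-first (by latitude); propagation along
#' a parental edge stops early when the hash of the updated
#' (haplotype, interval) pair equals the pre-update hash -- coalescences
#' with untouched lineages typically stop the spread well below the root.
#'
#' `method = "full"` recomputes every vertex bottom-up with no hash gate;
#' it is the reference the gated path is tested against.
#'
#' @param g a genealogy, modified in place.
#' @param seeds edge ids whose child vertices start the frontier.
#' @param method `"hash"` (gated early termination) or `"full"`.
#' @return The genealogy, invisibly.
#' @export
update_upstream <- function(g, seeds, method = c("hash", "full")) {
  method <- match.arg(method)
  if (method == "full") {
    ord <- order(g$lat)
    for (v in ord) {
      if (g$kind[v] == KIND_LEAF) next
      g$hap[[v]] <- recompute_hap(g, v)
      for (e in g$up[[v]]) g$e_anc[[e]] <- recompute_edge_anc(g, e)
    }
    return(invisible(g))
  }
  pend <- unique(g$e_parent[seeds])
  visited_guard <- 0L
  nmax <- 4L * length(g$lat) + 16L
  while (length(pend) > 0L) {
    visited_guard <- visited_guard + 1L
    if (visited_guard > nmax * 4L)
      stop("update_upstream: propagation failed to settle (corrupt graph?)")
    i <- which.min(g$lat[pend])
    v <- pend[i]
    pend <- pend[-i]
    if (g$kind[v] == KIND_LEAF) next
    old_hap <- g$hap[[v]]
    g$hap[[v]] <- recompute_hap(g, v)
    for (e in g$up[[v]]) {
      old <- state_hash(g, old_hap, g$e_anc[[e]])
      g$e_anc[[e]] <- recompute_edge_anc(g, e)
      new <- edge_state_hash(g, e)
      if (!identical(old, new)) {
        u <- g$e_parent[e]
        if (!(u %in% pend)) pend <- c(pend, u)
      }
    }
  }
  invisible(g)
}
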