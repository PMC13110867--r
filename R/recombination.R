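#' Recombination event classification
#'
#' Classifies a potential recombination on edge `e` at breakpoint `b`
#' by where the edge's ancestral material falls relative to `b`: type 1
#' has ancestral material on both sides with `b` inside material, type 2
#' has material on both sides with `b` in a non-ancestral gap of the
#' closure, types 3 and 4 have material only left / only right of `b`,
#' and type 5 occurs on a fully non-ancestral edge. Only types 1 and 2
#' contribute to the structure of the sample.
#'
#' @param g a genealogy.
#' @param e an edge id.
#' @param b breakpoint position (bp).
#' @return An integer in 1..5.
#' @export
classify_event <- function(g, e, b) {
  anc <- g$e_anc[[e]]
  if (iset_is_empty(anc)) return(5L)
  left <- !iset_is_empty(iset_intersect(anc, iset(0, b)))
  right <- !iset_is_empty(iset_intersect(anc, iset_raw(c(b, Inf))))
  if (left && right) {
    if (iset_contains(anc, b)) 1L else 2L
  } else if (left) 3L
  else if (right) 4L
  else 5L
}

# clamp a location strictly inside an open interval
clamp_open <- function(x, lo, hi) {
  eps <- (hi - lo) * 1e-9
  min(max(x, lo + eps), hi - eps)
}

#' Apply a recombination-and-recoalescence event
#'
#' Splits the recombination edge at latitude `l_r`, inserting a
#' recombination vertex whose mask routes `[0, b')` to the left parental
#' edge and `[b', Inf)` to the right, then recoalesces the right lineage:
#' either by splitting the recoalescence edge at `l_c` (inserting a
#' coalescence vertex) or, when `e_c` is `NA` and `l_c` exceeds the grand
#' MRCA's latitude, by promoting a fresh root whose children are the old
#' root and the recombination vertex. Haplotypes and ancestral intervals
#' upstream are then repaired by [update_upstream()].
#'
#' @param g a genealogy, modified in place.
#' @param ev a list with `e_r`, `bprime`, `l_r`, `e_c` (edge id or `NA`
#'   for above-root recoalescence), `l_c`, and optional `kind`.
#' @param update `"hash"` or `"full"` propagation.
#' @return The genealogy, invisibly; the event (with created vertex ids)
#'   is appended as attribute fields `v_r`, `v_c` of `g$last_event`.
#' @export
apply_rr <- function(g, ev, update = c("hash", "full")) {
  update <- match.arg(update)
  e_r <- ev$e_r; bprime <- ev$bprime; l_r <- ev$l_r
  e_c <- ev$e_c; l_c <- ev$l_c
  if (!g$e_active[e_r]) stop("invalid event: recombination edge is not active")
  c_r <- g$e_child[e_r]; p_r <- g$e_parent[e_r]
  if (!(l_r > g$lat[c_r] && l_r < g$lat[p_r]))
    stop("invalid event: l_r outside the recombination edge's span")
  if (!(l_c > l_r)) stop("invalid event: l_c <= l_r")
  I <- g$e_anc[[e_r]]
  side_r <- g$e_side[e_r]
  left_mask <- iset(0, bprime)
  right_mask <- iset_raw(c(bprime, Inf))

  v_r <- g_add_vertex(g, l_r, KIND_RECOMB, g$hap[[c_r]])
  g$mask_left[[v_r]] <- left_mask
  g$mask_right[[v_r]] <- right_mask
  g_del_edge(g, e_r)
  g_add_edge(g, c_r, v_r, I, side = side_r)
  e_left <- g_add_edge(g, v_r, p_r, iset_intersect(left_mask, I), side = 1L)
  right_anc <- iset_intersect(right_mask, I)

  if (identical(e_c, e_r)) e_c <- e_left    # bubble: recoalesce onto own lineage
  seeds <- e_left
  if (is.na(e_c)) {
    if (!(l_c > g$lat[g$root]))
      stop("invalid event: above-root recoalescence below the gMRCA")
    old_root <- g$root
    v_c <- g_add_vertex(g, l_c, KIND_COAL, g$hap[[old_root]])
    g_add_edge(g, old_root, v_c, child_union(g, old_root))
    g_add_edge(g, v_r, v_c, right_anc, side = 2L)
    g$hap[[v_c]] <- recompute_hap(g, v_c)
    g$root <- v_c
  } else {
    if (!g$e_active[e_c]) stop("invalid event: recoalescence edge is not active")
    c_c <- g$e_child[e_c]; p_c <- g$e_parent[e_c]
    if (!(l_c > g$lat[c_c] && l_c < g$lat[p_c]))
      stop("invalid event: l_c outside the recoalescence edge's span")
    I_c <- g$e_anc[[e_c]]
    side_c <- g$e_side[e_c]
    v_c <- g_add_vertex(g, l_c, KIND_COAL, g$hap[[c_c]])
    g_del_edge(g, e_c)
    g_add_edge(g, c_c, v_c, I_c, side = side_c)
    e_upper <- g_add_edge(g, v_c, p_c, iset_empty())
    g_add_edge(g, v_r, v_c, right_anc, side = 2L)
    g$hap[[v_c]] <- recompute_hap(g, v_c)
    g$e_anc[[e_upper]] <- recompute_edge_anc(g, e_upper)
    seeds <- c(seeds, e_upper)
  }
  g$n_recomb <- g$n_recomb + 1L
  update_upstream(g, seeds, method = update)
  g$last_event <- c(ev, list(v_r = v_r, v_c = v_c))
  invisible(g)
}

#' Sample an unrestricted recombination-and-recoalescence event
#'
#' Draws an event from the (restricted-support) coalescent-with-
#' recombination law: a recombination edge proportional to branch length,
#' a breakpoint uniform on the interior of the closure of the edge's
#' ancestral material (which confines events to types 1 and 2), a
#' recombination latitude Beta(2,2)-scaled along the edge (favouring
#' central locations over the uniform law to avoid pathologically short
#' branches), and a recoalescence latitude from the inhomogeneous Poisson
#' process whose rate is the number of live branches (rate 1 above the
#' root), by time-scale transformation; the recoalescence edge is uniform
#' among branches at that latitude.
#'
#' @param g a genealogy.
#' @param window_pos optional position on which a Markov window is
#'   centered.
#' @param window_width window half-width `w` in bp (`Inf` = no
#'   approximation).
#' @return An event list as consumed by [apply_rr()], `kind`
#'   `"unrestricted"`.
#' @export
sample_unrestricted_rr <- function(g, window_pos = NULL, window_width = Inf) {
  es <- active_edges(g)
  es <- es[!vapply(es, function(e) iset_is_empty(g$e_anc[[e]]), logical(1))]
  if (!is.null(window_pos))
    es <- window_filter(g, es, window_pos, window_width)
  if (length(es) == 0L) stop("no candidate recombination edge")
  spans <- vapply(es, function(e) edge_span(g, e), numeric(1))
  e_r <- es[sample.int(length(es), 1L, prob = spans)]
  cl <- unclass(iset_closure(g$e_anc[[e_r]]))
  bprime <- stats::runif(1L, cl[1L], cl[2L])
  lo <- g$lat[g$e_child[e_r]]; hi <- g$lat[g$e_parent[e_r]]
  l_r <- clamp_open(lo + (hi - lo) * stats::rbeta(1L, 2, 2), lo, hi)
  # recoalescence: piecewise-constant rate = number of overlapping branches
  cand <- es
  res <- ppp_first_event(g, l_r, cand, above_root_rate = 1)
  l_c <- res$l_c
  if (res$above_root) {
    e_c <- NA_integer_
  } else {
    over <- cand[g$lat[g$e_child[cand]] < l_c & g$lat[g$e_parent[cand]] > l_c]
    if (length(over) == 0L) stop("internal: no branch at the sampled latitude")
    e_c <- over[sample.int(length(over), 1L)]
    if (e_c == e_r && l_c <= l_r)
      l_c <- clamp_open(l_c, l_r, g$lat[g$e_parent[e_r]])
  }
  list(e_r = e_r, bprime = bprime, l_r = l_r, e_c = e_c, l_c = l_c,
       kind = "unrestricted")
}

# exact first-event draw from the inhomogeneous PPP whose intensity at
# latitude t is the number of candidate edges overlapping t; above the
# root the intensity is `above_root_rate`
ppp_first_event <- function(g, l_r, cand, above_root_rate = 1) {
  root_lat <- g$lat[g$root]
  cuts <- sort(unique(c(l_r, g$lat[g$lat > l_r], root_lat)))
  cuts <- cuts[cuts <= root_lat]
  E <- stats::rexp(1L)
  acc <- 0
  if (length(cuts) >= 2L) {
    for (i in seq_len(length(cuts) - 1L)) {
      mid <- (cuts[i] + cuts[i + 1L]) / 2
      k <- sum(g$lat[g$e_child[cand]] < mid & g$lat[g$e_parent[cand]] > mid)
      seg <- cuts[i + 1L] - cuts[i]
      if (acc + k * seg >= E && k > 0L) {
        return(list(l_c = cuts[i] + (E - acc) / k, above_root = FALSE))
      }
      acc <- acc + k * seg
    }
  }
  list(l_c = root_lat + (E - acc) / above_root_rate, above_root = TRUE)
}

#' Markov window filter
#'
#' Excludes every edge whose ancestral material does not intersect the
#' window `[p - w, p + w]` centered on the event position `p`. Excluded
#' edges are dropped both as candidates and from recoalescence-rate
#' computations. `w = Inf` is the identity; `w = 0` keeps only edges
#' ancestral at `p` (a first-order Markov approximation of the
#' recombination process).
#'
#' @param g a genealogy.
#' @param edges edge ids.
#' @param p window center (bp).
#' @param w half-width in bp, `[0, Inf]`.
#' @return The retained edge ids.
#' @export
window_filter <- function(g, edges, p, w) {
  if (is.infinite(w)) return(edges)
  if (w < 0) stop("window width must be nonnegative")
  lo <- max(0, p - w)
  edges[vapply(edges, function(e) {
    anc <- g$e_anc[[e]]
    if (iset_is_empty(anc)) return(FALSE)
    iset_contains(anc, p) ||
      !iset_is_empty(iset_intersect(anc, iset(lo, p + w)))
  }, logical(1))]
}

# status of the marker-k material that a lineage recoalescing onto edge f
# would meet: the allele of f's child if f is ancestral at k's position,
# otherwise the allele of the first ancestral vertex upstream of f's
# child end. Returns list(bit, vertex).
insertion_status <- function(g, f, k) {
  p <- g$sample$positions[k]
  if (iset_contains(g$e_anc[[f]], p)) {
    v <- g$e_child[f]
    return(list(bit = vertex_bit(g, v, k), vertex = v))
  }
  upstream_status(g, g$e_parent[f], k)
}

# first vertex at or above v that carries ancestral material for marker k,
# and its allele there
upstream_status <- function(g, v, k) {
  p <- g$sample$positions[k]
  repeat {
    kids <- g$down[[v]]
    if (length(kids) > 0L &&
        any(vapply(kids, function(e) iset_contains(g$e_anc[[e]], p), logical(1))))
      return(list(bit = vertex_bit(g, v, k), vertex = v))
    ups <- g$up[[v]]
    if (length(ups) == 0L) return(list(bit = vertex_bit(g, v, k), vertex = v))
    if (length(ups) == 1L) {
      v <- g$e_parent[ups[1L]]
    } else {
      # recombination vertex: route by mask side
      e <- if (iset_contains(edge_side_mask(g, ups[1L]), p)) ups[1L] else ups[2L]
      v <- g$e_parent[e]
    }
  }
}

#' Lower bound of the breakpoint support
#'
#' The support of a constrained breakpoint extends left of the previous
#' marker `m'` as far as every intervening marker `k` satisfies one of:
#' the recombination and recoalescence lineages agree at `k`; the
#' recombination edge is not ancestral for `k`; or the recoalescence edge
#' is not ancestral for `k` and the first ancestral vertex upstream of the
#' insertion point carries the recombination lineage's allele. Under any
#' of these no new mutation edge can appear at `k` in `[b', m)`. The
#' bound is additionally clipped so that ancestral material of the
#' recombination edge remains on the left of the breakpoint (discarding
#' would-be type 4 events).
#'
#' @param g a genealogy.
#' @param m 1-based index of the focal (inconsistent) marker.
#' @param e_r recombination edge id.
#' @param e_c recoalescence edge id, or `NA` for above-root recoalescence.
#' @return The lower support bound `b'_i` (bp).
#' @export
breakpoint_lower_bound <- function(g, m, e_r, e_c) {
  pos <- g$sample$positions
  v_r <- g$e_child[e_r]
  anc_r <- g$e_anc[[e_r]]
  anc_c <- if (is.na(e_c)) child_union(g, g$root) else g$e_anc[[e_c]]
  v_c_child <- if (is.na(e_c)) g$root else g$e_child[e_c]
  bound <- if (m >= 2L) pos[m - 1L] else 0
  k <- m - 1L
  while (k >= 1L) {
    # the recombination lineage carries marker k only if e_r is ancestral
    # there; if so, the merge happens at the recoalescence point when e_c
    # carries k (alleles must agree), otherwise at the first ancestral
    # vertex upstream (whose allele must match the lineage's)
    ok <- if (!iset_contains(anc_r, pos[k])) {
      TRUE
    } else if (iset_contains(anc_c, pos[k])) {
      vertex_bit(g, v_r, k) == vertex_bit(g, v_c_child, k)
    } else {
      st <- if (is.na(e_c)) list(bit = vertex_bit(g, g$root, k))
      else upstream_status(g, g$e_parent[e_c], k)
      st$bit == vertex_bit(g, v_r, k)
    }
    if (!ok) break
    bound <- if (k >= 2L) pos[k - 1L] else 0
    k <- k - 1L
  }
  # type-4 discard: keep material of e_r strictly left of b'
  a_min <- if (iset_is_empty(anc_r)) 0 else unclass(anc_r)[1L]
  max(bound, a_min)
}

#' Sample a constrained breakpoint
#'
#' Uniform on `[b_lo, m_pos)`: the uniform law over the admissible support
#' keeps every admissible type 2 position available while avoiding the
#' numerical fragility of a truncated exponential.
#'
#' @param b_lo lower support bound.
#' @param m_pos focal marker position (exclusive upper end).
#' @return A breakpoint strictly inside `(b_lo, m_pos)`.
#' @export
sample_breakpoint <- function(b_lo, m_pos) {
  if (!(b_lo < m_pos)) stop("empty breakpoint support")
  clamp_open(stats::runif(1L, b_lo, m_pos), b_lo, m_pos)
}

# contracted-chain bookkeeping shared by candidate enumeration ------------

# chains of the marginal tree at p, keyed by bottom contracted vertex;
# each chain lists ARG edges bottom-to-top
chain_of <- function(mt, v) mt$chain[[v]]

chain_top_map <- function(mt) {
  tops <- integer(0)
  for (v in mt$cvert) {
    ch <- mt$chain[[v]]
    if (length(ch) > 0L) tops[as.character(ch[length(ch)])] <- v
  }
  tops
}

#' Derived recombination candidates at a marker
#'
#' Coalescing two of the marker's mutation edges removes exactly one
#' mutation, and the recombination does not need to sit on the mutation
#' edge itself: any edge of its downstream chain of marginally
#' sibling-less edges detaches the same derived material. Each candidate
#' is weighted by its branch length (difference in latitude of its
#' incident vertices).
#'
#' @param g a genealogy.
#' @param M mutation edge ids at the marker (from [next_inconsistent()]).
#' @param marker 1-based focal marker index.
#' @return A data frame with columns `edge`, `weight`, `group` (index into
#'   `M`), `kind`.
#' @export
derived_candidates <- function(g, M, marker, mt = NULL) {
  p <- g$sample$positions[marker]
  if (is.null(mt)) mt <- marginal_tree(g, p)
  tops <- chain_top_map(mt)
  out <- list()
  for (i in seq_along(M)) {
    v <- tops[as.character(M[i])]
    if (is.na(v)) next                      # defensive: M must be chain tops
    ch <- mt$chain[[v]]
    out[[i]] <- data.frame(edge = ch,
                           weight = vapply(ch, function(e) edge_span(g, e),
                                           numeric(1)),
                           group = i, kind = "derived",
                           stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(edge = integer(0), weight = numeric(0),
                      group = integer(0), kind = character(0)))
  do.call(rbind, out)
}

#' Wild recombination candidates at a marker
#'
#' A recombination on a wild edge removes at least one mutation when its
#' marginal brother is a mutation edge and their uncle is one too: the two
#' derived clades become marginal siblings, and the reduction propagates
#' upward through any further derived uncles. As in the derived case the
#' event may sit anywhere along the wild chain of marginally sibling-less
#' edges, weighted by branch length.
#'
#' @inheritParams derived_candidates
#' @return A data frame with columns `edge`, `weight`, `group` (bottom
#'   contracted vertex id), `kind`.
#' @export
wild_candidates <- function(g, M, marker, mt = NULL) {
  p <- g$sample$positions[marker]
  if (is.null(mt)) mt <- marginal_tree(g, p)
  out <- list()
  for (v in mt$cvert) {
    if (vertex_bit(g, v, marker) != 0L) next
    cu <- mt$cparent[v]
    if (is.na(cu)) next
    sibs <- mt$cchildren[[as.character(cu)]]
    b <- setdiff(sibs, v)
    if (length(b) != 1L || vertex_bit(g, b, marker) != 1L) next
    cw <- mt$cparent[cu]
    if (is.na(cw)) next
    u0 <- setdiff(mt$cchildren[[as.character(cw)]], cu)
    if (length(u0) != 1L || vertex_bit(g, u0, marker) != 1L) next
    ch <- mt$chain[[v]]
    out[[length(out) + 1L]] <-
      data.frame(edge = ch,
                 weight = vapply(ch, function(e) edge_span(g, e), numeric(1)),
                 group = v, kind = "wild", stringsAsFactors = FALSE)
  }
  if (length(out) == 0L)
    return(data.frame(edge = integer(0), weight = numeric(0),
                      group = integer(0), kind = character(0)))
  do.call(rbind, out)
}

# edges of the focal chain at or above the chosen recombination edge, and
# the vertices a reattachment must avoid meeting first
chain_exclusions <- function(g, mt, bottom, e_r) {
  ch <- mt$chain[[bottom]]
  j <- match(e_r, ch)
  above <- ch[j:length(ch)]
  list(edges = above, vertices = g$e_parent[above])
}

# A wild detachment flips its parent junction from wild to derived, and
# the flip cascades upward while every other child at the next junction is
# derived (each flip merges mutation edges -- that is the reduction).
# Re-attaching wild material anywhere on the cascade path (the flipping
# junctions and the pass-through vertices between them) would break the
# merge, so those vertices are excluded as reattachment meeting points.
wild_flip_path <- function(g, mt, bottom, marker) {
  excl <- integer(0)
  x <- mt$cparent[bottom]
  if (is.na(x)) return(excl)
  repeat {
    excl <- c(excl, x)
    y <- mt$cparent[x]
    if (is.na(y)) break
    interior <- g$e_parent[mt$chain[[x]]]
    if (length(interior) > 1L) excl <- c(excl, interior[-length(interior)])
    others <- setdiff(mt$cchildren[[as.character(y)]], x)
    if (length(others) > 0L &&
        all(vapply(others, function(v) vertex_bit(g, v, marker), integer(1)) == 1L)) {
      x <- y
    } else break
  }
  excl
}

#' Derived recoalescence
#'
#' Coalescence occurs at unit rate with each admissible edge: those whose
#' insertion point meets derived material at the focal marker (a mutation
#' edge, anything below one, or a non-ancestral edge leading into derived
#' material). Each edge's probability is proportional to its length minus
#' any section below the admissible minimum latitude, and the location on
#' the chosen edge is Beta(2,2)-scaled on the admissible portion.
#'
#' @param g a genealogy.
#' @param l_r recombination latitude (lower latitude bound).
#' @param edges admissible recoalescence edge ids.
#' @return A list with `e_c` and `l_c`, or `NULL` when no edge has
#'   positive admissible length.
#' @export
sample_derived_recoalescence <- function(g, l_r, edges) {
  lo <- pmax(l_r, g$lat[g$e_child[edges]])
  wt <- g$lat[g$e_parent[edges]] - lo
  keep <- wt > 0
  if (!any(keep)) return(NULL)
  edges <- edges[keep]; lo <- lo[keep]; wt <- wt[keep]
  i <- sample.int(length(edges), 1L, prob = wt)
  l_c <- clamp_open(lo[i] + wt[i] * stats::rbeta(1L, 2, 2),
                    g$lat[g$e_child[edges[i]]], g$lat[g$e_parent[edges[i]]])
  if (l_c <= l_r) l_c <- clamp_open(l_c, l_r, g$lat[g$e_parent[edges[i]]])
  list(e_c = edges[i], l_c = l_c)
}

#' Wild recoalescence latitude
#'
#' The latitude of a wild recoalescence is the first event of an
#' inhomogeneous Poisson process whose intensity at latitude `t` is the
#' number of admissible branches overlapping `t` (constant rate 1 above
#' the grand MRCA, where a lineage always finds the root lineage). The
#' cumulative intensity is evaluated by quadrature on a logarithmic grid
#' of latitudes (the ARG's topology thins out with height) in a single
#' pass, and inverted (time-scale transformation).
#'
#' @param g a genealogy.
#' @param l_r recombination latitude.
#' @param edges candidate edge ids (may be empty).
#' @param grid_size number of quadrature nodes (default 25).
#' @return A latitude `l_c > l_r`.
#' @export
sample_wild_recoalescence_latitude <- function(g, l_r, edges,
                                               grid_size = getOption("sarg.grid", 25L)) {
  root_lat <- g$lat[g$root]
  E <- stats::rexp(1L)
  if (l_r >= root_lat || length(edges) == 0L)
    return(max(l_r, root_lat) + E)        # above-root regime only, rate 1
  span <- root_lat - l_r
  offs <- c(0, exp(seq(log(span * 1e-6), log(span), length.out = grid_size)))
  nodes <- l_r + offs
  acc <- 0
  clo <- g$lat[g$e_child[edges]]; chi <- g$lat[g$e_parent[edges]]
  for (i in seq_len(length(nodes) - 1L)) {
    mid <- (nodes[i] + nodes[i + 1L]) / 2
    k <- sum(clo < mid & chi > mid)
    seg <- nodes[i + 1L] - nodes[i]
    if (k > 0L && acc + k * seg >= E)
      return(nodes[i] + (E - acc) / k)
    acc <- acc + k * seg
  }
  root_lat + (E - acc)                      # above-root regime, rate 1
}

#' Recombination-mask update for a multiple crossing over
#'
#' A further crossover at `bprime` on the parental edge that currently
#' owns the rightmost portion of the mask (the `+Inf` tail) is absorbed
#' into the existing recombination vertex by intersecting that side with
#' `[0, b')` and giving the other side the union with `[b', Inf)`. The
#' two sides always remain a partition of `[0, Inf)`.
#'
#' @param tail_side the mask currently containing the `+Inf` tail.
#' @param other_side the complementary mask.
#' @param bprime the new crossover position.
#' @return A list with the updated `tail_side` and `other_side`.
#' @export
mco_masks <- function(tail_side, other_side, bprime) {
  list(tail_side = iset_intersect(tail_side, iset(0, bprime)),
       other_side = iset_union(other_side, iset_raw(c(bprime, Inf))))
}

#' Multiple crossing over via mask editing
#'
#' When the drawn recombination edge is the parental edge of a
#' recombination vertex that carries the rightmost portion of the mask (it
#' owns the `+Inf` tail), the same reduction can be achieved without new
#' vertices: intersect that side of the mask with `[0, b')` and give the
#' other side the union with `[b', Inf)`, rerouting the focal material
#' through the other parental edge, where it coalesces with that edge's
#' sibling. The event is attempted only if the sibling meets the required
#' allele and, once applied on a scratch copy, is committed only when the
#' focal marker's mutation count strictly decreases and no marker in
#' `[b', m)` gains mutations.
#'
#' @param g a genealogy.
#' @param e the drawn candidate edge.
#' @param marker focal marker index.
#' @param allele 1 for a derived event, 0 for wild.
#' @return The modified genealogy (committed in place) with attribute-like
#'   field `g$last_event$kind == "mco"`, or `NULL` when the conditions are
#'   not met.
#' @export
try_mco <- function(g, e, marker, allele) {
  v_k <- g$e_child[e]
  if (g$kind[v_k] != KIND_RECOMB) return(NULL)
  side <- g$e_side[e]
  if (side == 0L) return(NULL)
  mask_e <- edge_side_mask(g, e)
  ends <- unclass(mask_e)
  if (length(ends) == 0L || is.finite(ends[length(ends)])) return(NULL)
  ups <- g$up[[v_k]]
  e_o <- setdiff(ups, e)
  if (length(e_o) != 1L) return(NULL)
  u_o <- g$e_parent[e_o]
  if (g$kind[u_o] != KIND_COAL) return(NULL)
  sib <- setdiff(g$down[[u_o]], e_o)
  if (length(sib) != 1L) return(NULL)
  p <- g$sample$positions[marker]
  st <- insertion_status(g, sib, marker)
  if (st$bit != allele) return(NULL)
  # breakpoint: conditions computed against the sibling's lineage
  b_lo <- breakpoint_lower_bound(g, marker, e, sib)
  if (!(b_lo < p)) return(NULL)
  bprime <- sample_breakpoint(b_lo, p)
  lo_k0 <- pos_to_idx(g$sample, max(bprime, g$sample$positions[1L]))
  check0 <- max(1L, lo_k0):marker
  before <- vapply(check0, function(k) length(count_mutations_at(g, k)),
                   integer(1))
  names(before) <- check0
  g2 <- g_copy(g)
  if (side == 1L) {
    upd <- mco_masks(mask_e, g2$mask_right[[v_k]], bprime)
    g2$mask_left[[v_k]] <- upd$tail_side
    g2$mask_right[[v_k]] <- upd$other_side
  } else {
    upd <- mco_masks(mask_e, g2$mask_left[[v_k]], bprime)
    g2$mask_right[[v_k]] <- upd$tail_side
    g2$mask_left[[v_k]] <- upd$other_side
  }
  g2$e_anc[[e]] <- recompute_edge_anc(g2, e)
  g2$e_anc[[e_o]] <- recompute_edge_anc(g2, e_o)
  update_upstream(g2, c(e, e_o))
  after <- vapply(check0, function(k) length(count_mutations_at(g2, k)),
                  integer(1))
  if (after[length(check0)] >= before[length(check0)]) return(NULL)
  if (any(after[-length(check0)] > before[-length(check0)])) return(NULL)
  # commit
  for (nm in ls(g2, all.names = TRUE)) assign(nm, get(nm, envir = g2), envir = g)
  g$last_event <- list(e_r = e, bprime = bprime, kind = "mco", v_r = v_k)
  g
}
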