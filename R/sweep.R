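#' Sweep configuration
#'
#' @param window Markov-window half-width `w` in bp: `Inf` disables the
#'   approximation, `0` restricts candidate recombination and
#'   recoalescence edges to the current marginal tree (a first-order
#'   Markov scheme).
#' @param grid_size quadrature grid size for wild recoalescence latitudes.
#' @param seed optional RNG seed.
#' @param max_attempts cap on rejected event proposals per marker before
#'   aborting with diagnostics.
#' @return A `sweep_config` list.
#' @export
sweep_config <- function(window = Inf, grid_size = 25L, seed = NULL,
                         max_attempts = 500L) {
  if (!(window >= 0)) stop("window must be in [0, Inf]")
  structure(list(window = window, grid_size = grid_size, seed = seed,
                 max_attempts = max_attempts), class = "sweep_config")
}

# per-edge insertion status and window admissibility, computed once per
# event and shared across proposal attempts (the graph is unchanged while
# proposals are rejected)
event_status_cache <- function(g, marker, p, config) {
  es <- active_edges(g)
  es <- window_filter(g, es, p, config$window)
  st <- lapply(es, insertion_status, g = g, k = marker)
  list(edges = es,
       bit = vapply(st, `[[`, integer(1), "bit"),
       vertex = vapply(st, `[[`, integer(1), "vertex"))
}

# admissible recoalescence edges for a constrained event on e_r:
# everything except the vanishing chain pieces, filtered by the Markov
# window and by the allele the reattachment would meet
recoal_support <- function(g, mt, e_r, allele, bottom, marker, cache,
                           wild = FALSE) {
  excl <- chain_exclusions(g, mt, bottom, e_r)
  if (wild)
    excl$vertices <- c(excl$vertices, wild_flip_path(g, mt, bottom, marker))
  keep <- cache$bit == allele & !(cache$vertex %in% excl$vertices) &
    !(cache$edges %in% c(excl$edges, e_r))
  list(es0 = cache$edges[keep], excl = excl)
}

# one constrained event at the focal marker; modifies g in place and
# returns the event descriptor
constrained_event <- function(g, marker, M, config) {
  p <- g$sample$positions[marker]
  mt <- marginal_tree(g, p)
  dc <- derived_candidates(g, M, marker, mt = mt)
  wc <- wild_candidates(g, M, marker, mt = mt)
  tops <- chain_top_map(mt)
  cache <- event_status_cache(g, marker, p, config)
  cand <- rbind(dc, wc)
  if (nrow(cand) == 0L)
    stop("no constrained candidate at marker ", marker)
  keep <- window_filter(g, cand$edge, p, config$window)
  cand <- cand[cand$edge %in% keep, , drop = FALSE]
  if (nrow(cand) == 0L)
    stop("window filter removed every candidate at marker ", marker)

  c_edge <- cand$edge; c_weight <- cand$weight
  c_group <- cand$group; c_kind <- cand$kind
  guided <- FALSE
  for (attempt in seq_len(config$max_attempts)) {
    if (attempt > 50L && !guided) {
      # persistent rejection: keep only rows whose recoalescence support
      # is provably nonempty (at least one derived event always is)
      guided <- TRUE
      viable <- vapply(seq_along(c_edge), function(r) {
        if (c_kind[r] == "wild") return(TRUE)  # above-root regime always open
        bt <- tops[as.character(M[c_group[r]])]
        sup <- recoal_support(g, mt, c_edge[r], 1L, bt, marker, cache, wild = FALSE)
        length(sup$es0) > 0L &&
          g$lat[g$e_child[c_edge[r]]] < min(g$lat[g$e_parent[c_edge[r]]],
                                            max(g$lat[g$e_parent[sup$es0]]))
      }, logical(1))
      if (!any(viable))
        stop("no viable constrained event at marker ", marker)
      c_edge <- c_edge[viable]; c_weight <- c_weight[viable]
      c_group <- c_group[viable]; c_kind <- c_kind[viable]
    }
    r <- sample.int(length(c_edge), 1L, prob = c_weight)
    e_r <- c_edge[r]
    allele <- if (c_kind[r] == "derived") 1L else 0L
    bottom <- if (c_kind[r] == "derived") tops[as.character(M[c_group[r]])] else c_group[r]
    # multiple crossing over: reuse an existing recombination vertex
    mco <- try_mco(g, e_r, marker, allele)
    if (!is.null(mco)) return(g$last_event)

    sup <- recoal_support(g, mt, e_r, allele, bottom, marker, cache,
                          wild = c_kind[r] == "wild")
    es0 <- sup$es0
    lo <- g$lat[g$e_child[e_r]]; hi <- g$lat[g$e_parent[e_r]]
    hi_eff <- hi
    if (guided && c_kind[r] == "derived") {
      # truncate the location support below the highest admissible partner
      if (length(es0) == 0L) next
      hi_eff <- min(hi, max(g$lat[g$e_parent[es0]]))
      if (!(lo < hi_eff)) next
    }
    l_r <- clamp_open(lo + (hi_eff - lo) * stats::rbeta(1L, 2, 2), lo, hi_eff)
    es <- es0[g$lat[g$e_parent[es0]] > l_r]
    if (c_kind[r] == "derived") {
      rec <- sample_derived_recoalescence(g, l_r, es)
      if (is.null(rec)) next                 # no admissible partner; resample
      e_c <- rec$e_c; l_c <- rec$l_c
    } else {
      l_c <- sample_wild_recoalescence_latitude(g, l_r, es, config$grid_size)
      if (l_c > g$lat[g$root]) {
        e_c <- NA_integer_
      } else {
        over <- es[g$lat[g$e_child[es]] < l_c & g$lat[g$e_parent[es]] > l_c]
        if (length(over) == 0L) {
          # quadrature landed in a coverage gap: snap to the nearest
          # covered latitude above
          above <- es[g$lat[g$e_parent[es]] > l_c]
          if (length(above) == 0L) { e_c <- NA_integer_; l_c <- g$lat[g$root] + stats::rexp(1L) }
          else {
            f <- above[which.min(pmax(g$lat[g$e_child[above]], l_c))]
            l_c <- clamp_open(max(l_c, g$lat[g$e_child[f]]),
                              g$lat[g$e_child[f]], g$lat[g$e_parent[f]])
            e_c <- f
          }
        } else e_c <- over[sample.int(length(over), 1L)]
      }
    }
    b_lo <- breakpoint_lower_bound(g, marker, e_r, e_c)
    if (!(b_lo < p)) next
    bprime <- sample_breakpoint(b_lo, p)
    ev <- list(e_r = e_r, bprime = bprime, l_r = l_r, e_c = e_c, l_c = l_c,
               kind = c_kind[r])
    apply_rr(g, ev)
    return(g$last_event)
  }
  stop("exhausted ", config$max_attempts, " event proposals at marker ",
       marker, " (", length(M), " mutation edges)")
}

#' Infer a sample-consistent ancestral recombination graph
#'
#' Starting from an initial coalescent tree, sweeps the markers left to
#' right: at each marker whose marginal tree carries two or more mutation
#' edges, constrained recombination-and-recoalescence events (derived,
#' wild, or mask-editing multiple crossovers, pooled and drawn by branch
#' length) are generated until the marker carries a single mutation, then
#' the sweep advances. Every constrained event strictly reduces the focal
#' marker's mutation count, and breakpoint supports are bounded so that
#' markers already processed never regain inconsistency, so the sweep
#' terminates with a genealogy that generates the sample under the
#' infinite-sites model.
#'
#' @param x an [arg_sample()] (an initial tree is built first) or a
#'   `coal_tree` from [build_tree()].
#' @param config a [sweep_config()].
#' @param metric,c0,t0 initial-tree parameters, used when `x` is a sample:
#'   see [metric()] and [tree_config()].
#' @param seed RNG seed for the whole run (tree + sweep).
#' @return A genealogy of class `c("arg", "genealogy")`.
#' @examples
#' sam <- simulate_sample(sim_spec(n = 6, seq_length = 1e4, rho = 1e-8,
#'                                 seed = 1))$sample
#' arg <- infer_arg(sam, seed = 1)
#' summary(arg)
#' @export
infer_arg <- function(x, config = sweep_config(), metric = "hamming",
                      c0 = 1, t0 = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (inherits(x, "arg_sample")) {
    met <- if (inherits(metric, "arg_metric")) metric else
      sarg::metric(metric, c0 = c0)
    g <- build_tree(x, tree_config(metric = met, t0 = t0))
  } else if (inherits(x, "coal_tree") || inherits(x, "genealogy")) {
    g <- x
  } else stop("x must be an arg_sample or a coal_tree")
  if (!is.null(config$seed) && is.null(seed)) set.seed(config$seed)
  s <- g$sample$s
  from <- 1L
  events <- 0L
  while (from <= s) {
    scan <- next_inconsistent(g, from)
    if (is.null(scan)) break
    m <- scan$marker_index
    M <- scan$mutation_edges
    count <- length(M)
    while (count >= 2L) {
      constrained_event(g, m, M, config)
      events <- events + 1L
      M <- count_mutations_at(g, m)
      if (length(M) >= count)
        stop("constrained event failed to reduce the mutation count at ",
             "marker ", m, " (", count, " -> ", length(M), ")")
      count <- length(M)
    }
    from <- m + 1L
  }
  g$sweep <- list(window = config$window, events = events)
  class(g) <- c("arg", "genealogy")
  g
}
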