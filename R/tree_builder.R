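#' Unnormalized Poisson log-weight for partner selection
#'
#' The probability of coalescing a candidate pair at biased distance
#' `d_ab` is proportional to `mu^d_ab / Gamma(d_ab + 1)`, an unnormalized
#' Poisson mass extended to non-integer distances. On the log scale this is
#' `d_ab * log(mu) - lgamma(d_ab + 1)`; `d_ab = Inf` yields `-Inf` (weight
#' zero). The log-gamma function is evaluated exactly ([lgamma()]), of
#' which Stirling's series is the asymptotic expansion.
#'
#' @param d_ab biased distance(s), in `[0, Inf]`.
#' @param mu global mutation rate, positive.
#' @return Log-weight(s); finite for finite `d_ab`.
#' @export
coal_log_weight <- function(d_ab, mu) {
  if (!(is.numeric(mu) && length(mu) == 1L && mu > 0))
    stop("mu must be a single positive number")
  if (any(d_ab < 0)) stop("distances must be nonnegative")
  out <- d_ab * log(mu) - lgamma(d_ab + 1)
  out[is.infinite(d_ab)] <- -Inf
  out
}

#' Gumbel-max categorical sampling
#'
#' Adds iid standard Gumbel noise to the log-weights and returns the
#' argmax, which is distributed categorically with probabilities
#' proportional to `exp(log_weights)` -- no normalizing constant is ever
#' formed, so weights spanning hundreds of orders of magnitude are handled
#' exactly.
#'
#' @param log_weights vector of log-weights; `-Inf` allowed.
#' @return The selected index.
#' @export
gumbel_argmax_select <- function(log_weights) {
  if (!any(is.finite(log_weights)))
    stop("no candidate with finite log-weight")
  gumb <- -log(stats::rexp(length(log_weights)))
  which.max(log_weights + gumb)
}

#' Secretary sampling: approximate argmax with early termination
#'
#' Perturbs each candidate with iid standard Gumbel noise (as in
#' [gumbel_argmax_select()]) but inspects candidates in the given order:
#' the first `ceiling(t0 * m)` form a learning phase whose running maximum
#' is recorded; afterwards the scheme stops at the first candidate
#' exceeding it. If none does, the overall argmax is returned after a full
#' traversal. For iid candidates the probability of early termination is
#' `1 - t0`, and the probability of returning the true argmax converges to
#' `t0 * (1 - log(t0))` as the number of candidates grows. `t0 = 1`
#' reduces to exact Gumbel-max sampling.
#'
#' @param log_weights candidate log-weights, in traversal order.
#' @param t0 learning-fraction threshold in `(0, 1]`.
#' @return A list with `index` (selected candidate), `traversed` (number of
#'   candidates inspected), `early` (logical: terminated before a full
#'   traversal), and `perturbed` (the full Gumbel-perturbed vector; only
#'   its first `traversed` entries were inspected by the scheme).
#' @export
secretary_select <- function(log_weights, t0) {
  if (!(is.numeric(t0) && length(t0) == 1L && t0 > 0 && t0 <= 1))
    stop("t0 must lie in (0, 1]")
  m <- length(log_weights)
  if (m == 0L) stop("no candidates")
  z <- log_weights - log(stats::rexp(m))    # Gumbel-perturbed values
  k <- ceiling(t0 * m)
  if (k < m) {
    learn_max <- max(z[seq_len(k)])
    rest <- which(z[(k + 1L):m] > learn_max)
    if (length(rest) > 0L) {
      stop_at <- k + rest[1L]
      return(list(index = stop_at, traversed = stop_at, early = stop_at < m,
                  perturbed = z))
    }
  }
  idx <- which.max(z)
  if (!is.finite(z[idx])) stop("no candidate with finite log-weight")
  list(index = idx, traversed = m, early = FALSE, perturbed = z)
}

#' Tree construction configuration
#'
#' @param metric a [metric()] (kind + bias `c0`).
#' @param t0 secretary threshold in `(0, 1]`; 1 means exact sampling.
#' @param seed optional RNG seed recorded in the output.
#' @return A `tree_config` list.
#' @export
tree_config <- function(metric = sarg::metric("hamming", c0 = 1), t0 = 1,
                        seed = NULL) {
  if (!inherits(metric, "arg_metric")) stop("metric must be a metric()")
  if (!(t0 > 0 && t0 <= 1)) stop("t0 must lie in (0, 1]")
  structure(list(metric = metric, t0 = t0, seed = seed), class = "tree_config")
}

logsumexp <- function(x) {
  x <- x[x > -Inf]
  if (length(x) == 0L) return(-Inf)
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Build an initial coalescent tree
#'
#' Repeats the following event `n - 1` times: draw a vertex `v_a` uniformly
#' among the live vertices, draw a partner `v_b` with probability
#' proportional to the unnormalized Poisson weight of their biased
#' haplotype distance (via the Gumbel trick, or the secretary scheme when
#' `t0 < 1`), and coalesce them into a vertex whose haplotype is the
#' GF(2) product (bitwise AND) of theirs. The latitude increment of each
#' event is exponential with rate equal to the number of live vertices.
#' With `c0 = Inf` and the left-marker distance, same-allele haplotypes
#' aggregate first and the resulting tree is consistent for marker 1.
#'
#' The unnormalized weights of the candidates actually traversed are
#' accumulated (stably, via log-sum-exp) into the tree's log-density
#' together with the exponential latitude terms; see [tree_log_density()].
#'
#' @param sample an [arg_sample()] with `n >= 2`.
#' @param config a [tree_config()].
#' @return A genealogy of class `c("coal_tree", "genealogy")`.
#' @export
build_tree <- function(sample, config = tree_config()) {
  if (!inherits(sample, "arg_sample")) stop("sample must be an arg_sample")
  n <- sample$n
  if (n < 2L) stop("need at least two haplotypes")
  if (!is.null(config$seed)) set.seed(config$seed)
  g <- g_new(sample)
  g$seed <- config$seed
  met <- config$metric
  mu <- sample$mu
  full <- iset_raw(c(0, sample$seq_length))
  live <- seq_len(n)
  lat <- 0
  logdens <- 0
  for (step in seq_len(n - 1L)) {
    k <- length(live)
    dt <- stats::rexp(1L, rate = k)
    lat <- lat + dt
    logdens <- logdens + stats::dexp(dt, rate = k, log = TRUE)
    lw_for <- function(va, cand) vapply(cand, function(vb) {
      coal_log_weight(biased_distance(met, g$hap[[va]], g$hap[[vb]]), mu)
    }, numeric(1))
    a_pos <- sample.int(k, 1L)
    va <- live[a_pos]
    cand <- live[-a_pos]
    if (length(cand) > 1L) cand <- sample(cand)    # fresh traversal order
    lw <- lw_for(va, cand)
    if (all(lw == -Inf)) {
      # degenerate bias (e.g. c0 = Inf): the drawn vertex has no partner
      # with positive weight; redraw among vertices that do, so that
      # finite-weight classes aggregate first
      for (va2 in sample(live)) {
        cand2 <- setdiff(live, va2)
        if (length(cand2) > 1L) cand2 <- sample(cand2)
        lw2 <- lw_for(va2, cand2)
        if (any(lw2 > -Inf)) { va <- va2; cand <- cand2; lw <- lw2; break }
      }
    }
    if (all(lw == -Inf)) {
      # no pair has positive weight anywhere: coalesce uniformly
      vb <- cand[sample.int(length(cand), 1L)]
      logdens <- logdens - log(length(cand))
    } else {
      sel <- secretary_select(lw, config$t0)
      vb <- cand[sel$index]
      # categorical term: chosen weight against the traversed normalizer
      logdens <- logdens + lw[sel$index] - logsumexp(lw[seq_len(sel$traversed)])
    }
    vc <- g_add_vertex(g, lat, KIND_COAL, seq_and(g$hap[[va]], g$hap[[vb]]))
    g_add_edge(g, va, vc, full)
    g_add_edge(g, vb, vc, full)
    live <- c(setdiff(live, c(va, vb)), vc)
  }
  g$root <- live[1L]
  g$logdens <- logdens
  class(g) <- c("coal_tree", "genealogy")
  g
}

#' Accumulated log-density of a built tree
#'
#' Sum over coalescence events of the chosen partner's log-weight minus
#' the log-sum of the weights traversed by the sampler, plus the
#' exponential log-densities of the latitude increments. Only trees built
#' by [build_tree()] carry the required traversal records.
#'
#' @param tree a `coal_tree`.
#' @return The accumulated log-density.
#' @export
tree_log_density <- function(tree) {
  if (!inherits(tree, "coal_tree"))
    stop("log-density is only recorded for trees built by build_tree()")
  tree$logdens
}
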