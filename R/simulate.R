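#' Simulation specification
#'
#' Parameters of the built-in neutral coalescent-with-recombination
#' simulator used for fixtures and calibration experiments. Rates are
#' per-bp, per-generation, diploid; the scaled locus-wide rates are
#' `theta = 4 Ne mu_prime l` and `R = 4 Ne rho l`.
#'
#' @param n number of haplotypes (>= 2).
#' @param seq_length sequence length `l` in bp.
#' @param Ne diploid effective population size.
#' @param mu_prime per-locus diploid mutation rate.
#' @param rho per-locus diploid recombination rate.
#' @param seed optional RNG seed.
#' @return A `sim_spec` list.
#' @export
sim_spec <- function(n, seq_length, Ne = 1e4, mu_prime = 1e-8, rho = 1e-8,
                     seed = NULL) {
  if (!(n >= 2)) stop("n must be at least 2")
  if (any(c(seq_length, Ne) <= 0) || any(c(mu_prime, rho) < 0))
    stop("rates must be nonnegative and sizes positive")
  structure(list(n = as.integer(n), seq_length = as.numeric(seq_length),
                 Ne = Ne, mu_prime = mu_prime, rho = rho, seed = seed),
            class = "sim_spec")
}

#' Simulate a haplotype sample under the neutral coalescent
#'
#' Hudson-style backward-in-time coalescent with recombination: lineages
#' carry the ancestral material of a single node as an interval set;
#' pairs coalesce at rate 1 (time in units of `2 Ne` generations),
#' lineages recombine at rate `R/2` scaled by the physical span of their
#' material, with breakpoints uniform on the span. Infinite-sites binary
#' mutations are then laid on the recorded node/edge tables at rate
#' `theta/2` per unit branch length, uniformly over physical extent; only
#' segregating sites are kept, each site mutating exactly once. The true
#' topology (node and edge tables in tree-sequence layout) is returned
#' alongside the sample for accuracy experiments.
#'
#' @param spec a [sim_spec()].
#' @return A list with elements `sample` (an [arg_sample()]) and `truth`
#'   (list of `nodes` and `edges` data frames, times in coalescent
#'   units).
#' @export
simulate_sample <- function(spec) {
  stopifnot(inherits(spec, "sim_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n; l <- spec$seq_length
  theta <- 4 * spec$Ne * spec$mu_prime * l
  R <- 4 * spec$Ne * spec$rho * l
  hmean <- sum(1 / seq_len(max(1L, n - 1L)))
  if (theta * hmean > 1e5 || R * hmean > 1e5)
    stop("rates imply more than 1e5 expected events at fixture scale; ",
         "reduce seq_length, Ne or the rates")
  # lineage state: node id + ancestral material
  lin_node <- seq_len(n)
  lin_mat <- lapply(seq_len(n), function(i) iset(0, l))
  node_time <- rep(0, n)
  ed_left <- ed_right <- ed_parent <- ed_child <- numeric(0)
  t <- 0
  while (length(lin_node) > 1L) {
    k <- length(lin_node)
    spans <- vapply(lin_mat, function(m) {
      cl <- unclass(iset_closure(m)); if (length(cl)) cl[2L] - cl[1L] else 0
    }, numeric(1))
    crate <- k * (k - 1) / 2
    rrate <- (R / 2) * sum(spans) / l
    t <- t + stats::rexp(1L, crate + rrate)
    if (stats::runif(1L) < crate / (crate + rrate)) {
      ij <- sample.int(k, 2L)
      i <- ij[1L]; j <- ij[2L]
      w <- length(node_time) + 1L
      node_time[w] <- t
      for (x in c(i, j)) {
        m <- unclass(lin_mat[[x]])
        if (length(m)) {
          a <- m[c(TRUE, FALSE)]; b <- m[c(FALSE, TRUE)]
          ed_left <- c(ed_left, a); ed_right <- c(ed_right, b)
          ed_parent <- c(ed_parent, rep(w, length(a)))
          ed_child <- c(ed_child, rep(lin_node[x], length(a)))
        }
      }
      newmat <- iset_union(lin_mat[[i]], lin_mat[[j]])
      lin_node <- c(lin_node[-c(i, j)], w)
      lin_mat <- c(lin_mat[-c(i, j)], list(newmat))
      # drop material that has reached its local MRCA (covered by exactly
      # one lineage): it can never coalesce again and carries no
      # segregating variation, so tracking it would only inflate the ARG
      if (length(lin_mat) > 1L) {
        trimmed <- lapply(seq_along(lin_mat), function(q) {
          cover <- Reduce(iset_union, lin_mat[-q])
          iset_intersect(lin_mat[[q]], cover)
        })
      } else trimmed <- list(iset_empty())
      keep <- !vapply(trimmed, iset_is_empty, logical(1))
      lin_node <- lin_node[keep]
      lin_mat <- trimmed[keep]
    } else {
      x <- sample.int(k, 1L, prob = spans)
      cl <- unclass(iset_closure(lin_mat[[x]]))
      b <- stats::runif(1L, cl[1L], cl[2L])
      left <- iset_intersect(lin_mat[[x]], iset(0, b))
      right <- iset_intersect(lin_mat[[x]], iset_raw(c(b, Inf)))
      if (iset_is_empty(left) || iset_is_empty(right)) next
      lin_mat[[x]] <- left
      lin_node <- c(lin_node, lin_node[x])
      lin_mat <- c(lin_mat, list(right))
    }
  }
  edges <- data.frame(left = ed_left, right = ed_right,
                      parent = ed_parent, child = ed_child)
  nodes <- data.frame(id = seq_along(node_time), time = node_time,
                      is_sample = seq_along(node_time) <= n)
  # infinite-sites mutations on the recorded topology
  elen <- (node_time[edges$parent] - node_time[edges$child]) *
    (edges$right - edges$left)
  area <- sum(elen)
  nmut <- stats::rpois(1L, theta / 2 * area / l)
  pos <- numeric(0); geno <- list()
  if (nmut > 0L) {
    eidx <- sample.int(nrow(edges), nmut, replace = TRUE, prob = elen)
    for (m in seq_len(nmut)) {
      e <- eidx[m]
      pp <- stats::runif(1L, edges$left[e], edges$right[e])
      der <- leaves_below(edges, n, edges$child[e], pp)
      if (length(der) == 0L || length(der) == n) next
      pos <- c(pos, pp)
      geno[[length(geno) + 1L]] <- der
    }
  }
  if (length(pos) > 0L) {
    keep <- !duplicated(pos)
    pos <- pos[keep]; geno <- geno[keep]
    o <- order(pos)
    pos <- pos[o]; geno <- geno[o]
  }
  mat <- matrix(0L, nrow = n, ncol = length(pos))
  for (j in seq_along(geno)) mat[geno[[j]], j] <- 1L
  sample <- arg_sample(mat, pos, l, Ne = spec$Ne, mu_prime = spec$mu_prime)
  list(sample = sample, truth = list(nodes = nodes, edges = edges))
}

# sample leaves inheriting from `node` at position `p` (node included if
# it is itself a leaf)
leaves_below <- function(edges, n, node, p) {
  out <- integer(0)
  stack <- node
  sel <- edges$left <= p & edges$right > p
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    if (v <= n) { out <- c(out, v); next }
    kids <- edges$child[sel & edges$parent == v]
    stack <- c(stack, kids)
  }
  sort(unique(out))
}

#' Pairwise coalescence times of a simulated truth topology
#'
#' @param truth the `truth` element returned by [simulate_sample()].
#' @param n sample size.
#' @param p position.
#' @return An `n x n` matrix of coalescence times (coalescent units).
#' @export
truth_pairwise_tmrca <- function(truth, n, p) {
  edges <- truth$edges
  sel <- edges$left <= p & edges$right > p
  par <- edges$parent[sel]; chi <- edges$child[sel]
  tm <- matrix(0, n, n)
  below <- function(v) {
    kids <- chi[par == v]
    if (length(kids) == 0L) return(if (v <= n) v else integer(0))
    sets <- lapply(kids, below)
    if (length(sets) >= 2L) {
      for (i in seq_len(length(sets) - 1L)) for (j in (i + 1L):length(sets)) {
        tv <- truth$nodes$time[v]
        tm[sets[[i]], sets[[j]]] <<- tv
        tm[sets[[j]], sets[[i]]] <<- tv
      }
    }
    unlist(sets)
  }
  root <- setdiff(par, chi)
  for (r in unique(root)) below(r)
  tm
}
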