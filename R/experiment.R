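#' Recombination-count experiment
#'
#' Infers many independent ARGs for one sample and tallies the number of
#' recombination vertices in each, the summary used to characterize the
#' parsimony behaviour of the method under different initial-tree
#' metrics.
#'
#' @param sample an [arg_sample()].
#' @param reps number of independent ARGs.
#' @param metric initial-tree metric name (`"hamming"` or `"left"`).
#' @param c0 metric bias.
#' @param t0 secretary threshold for tree building.
#' @param window Markov-window half-width.
#' @param seed master seed; per-replicate seeds are drawn from it.
#' @return A list with the per-replicate `counts` and their `mean`, `sd`,
#'   `min`, `max`.
#' @export
recombination_count_experiment <- function(sample, reps, metric = "hamming",
                                           c0 = 1, t0 = 1, window = Inf,
                                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, reps)
  counts <- vapply(seq_len(reps), function(i) {
    a <- infer_arg(sample, sweep_config(window = window), metric = metric,
                   c0 = c0, t0 = t0, seed = seeds[i])
    a$n_recomb
  }, integer(1))
  list(counts = counts, mean = mean(counts), sd = stats::sd(counts),
       min = min(counts), max = max(counts))
}

#' Hudson-Kaplan lower bound on the number of recombinations
#'
#' The classical four-gamete bound: every pair of markers exhibiting all
#' four gametes (00, 01, 10, 11) requires at least one recombination
#' strictly between them; the bound is the maximum number of pairwise
#' disjoint such open intervals, found greedily. Any genealogy generating
#' the sample under the infinite-sites model carries at least this many
#' recombination events.
#'
#' @param sample an [arg_sample()].
#' @return A nonnegative integer.
#' @export
hudson_kaplan_rmin <- function(sample) {
  m <- as.matrix(sample)
  s <- ncol(m)
  if (s < 2L) return(0L)
  lefts <- integer(0); rights <- integer(0)
  for (j in 2L:s) {
    for (i in (j - 1L):1L) {
      gam <- unique(paste0(m[, i], m[, j]))
      if (length(gam) == 4L) {
        lefts <- c(lefts, i); rights <- c(rights, j)
        break            # the tightest interval ending at j suffices
      }
    }
  }
  if (length(lefts) == 0L) return(0L)
  # maximal set of disjoint open intervals, greedy by right endpoint
  o <- order(rights)
  lefts <- lefts[o]; rights <- rights[o]
  count <- 0L
  last <- -Inf
  for (q in seq_along(lefts)) {
    if (lefts[q] >= last) {
      count <- count + 1L
      last <- rights[q]
    }
  }
  count
}
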