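test_that("coalescence log-weights are unnormalized Poisson masses", {
  expect_identical(coal_log_weight(0, mu = 3), 0)       # log Gamma(1) = 0
  expect_identical(coal_log_weight(Inf, mu = 3), -Inf)  # impossible pairing
  expect_equal(coal_log_weight(3, mu = 2), 3 * log(2) - log(6))
  expect_equal(exp(coal_log_weight(2.5, mu = 1.7)), 1.7^2.5 / gamma(3.5))
  expect_error(coal_log_weight(1, mu = 0), "positive")
  expect_error(coal_log_weight(-1, mu = 1), "nonnegative")
})

test_that("Gumbel-max selection samples the categorical distribution", {
  set.seed(108)
  lw <- c(-Inf, log(0.2), -Inf)
  expect_true(all(replicate(50, gumbel_argmax_select(lw)) == 2L))
  expect_error(gumbel_argmax_select(c(-Inf, -Inf)), "finite log-weight")
  # weights 1:3 => frequencies 0.25 / 0.75
  draws <- replicate(2e4, gumbel_argmax_select(log(c(1, 3))))
  p2 <- mean(draws == 2L)
  expect_lt(abs(p2 - 0.75), 4 * sqrt(0.75 * 0.25 / 2e4))
  # matches direct categorical sampling in distribution (chi-squared)
  w <- c(4, 1, 2, 3) / 10
  gm <- tabulate(replicate(2e4, gumbel_argmax_select(log(w))), 4)
  ct <- suppressWarnings(chisq.test(gm, p = w))
  expect_gt(ct$p.value, 1e-4)
})

test_that("secretary sampling terminates early with probability 1 - t0", {
  set.seed(109)
  m <- 40
  for (t0 in c(0.25, 0.5, 0.9)) {
    early <- replicate(3000, secretary_select(rnorm(m), t0)$early)
    se <- sqrt(t0 * (1 - t0) / 3000)
    expect_lt(abs(mean(early) - (1 - t0)), 4 * se + 1 / m)
  }
  # t0 = 1: exact sampling, never early
  r <- secretary_select(rnorm(10), 1)
  expect_false(r$early)
  expect_identical(r$traversed, 10L)
  expect_error(secretary_select(rnorm(3), 0), "t0")
})

test_that("two-haplotype trees have the forced shape", {
  sam <- arg_sample(rbind(c(1, 0), c(1, 1)), c(5, 15), 50)
  tr <- build_tree(sam, tree_config(seed = 11))
  expect_s3_class(tr, "coal_tree")
  expect_identical(sum(tr$kind == sarg:::KIND_COAL), 1L)
  expect_identical(as_bits(tr$hap[[tr$root]]),
                   as.integer(as_bits(sam$haplotypes[[1]]) &
                                as_bits(sam$haplotypes[[2]])))
  # density is the Exp(2) law of the height (partner choice forced)
  expect_equal(tree_log_density(tr), dexp(tr$lat[tr$root], 2, log = TRUE))
})

test_that("internal haplotypes obey the GF(2) AND rule", {
  sim <- sim_fixture(n = 9, seed = 13)
  tr <- build_tree(sim$sample, tree_config(seed = 2))
  for (v in which(tr$kind == sarg:::KIND_COAL)) {
    kids <- tr$e_child[tr$down[[v]]]
    expect_identical(unclass(tr$hap[[v]]),
                     unclass(seq_and(tr$hap[[kids[1]]], tr$hap[[kids[2]]])))
  }
  expect_true(validate_genealogy(tr)$structural_ok)
})

test_that("infinite left-marker bias aggregates allele classes first", {
  set.seed(110)
  for (rep in 1:10) {
    m <- matrix(sample(0:1, 7 * 5, TRUE), nrow = 7)
    m[, 1] <- c(0, 0, 0, 1, 1, 1, 1)[sample.int(7)]
    sam <- arg_sample(m, c(10, 20, 30, 40, 50), 100)
    tr <- build_tree(sam, tree_config(metric = metric("left", c0 = Inf)))
    # consistent for marker 1: at most one mutation edge there
    expect_lte(length(sarg:::count_mutations_at(tr, 1L)), 1L)
    # no cross-allele coalescence while both classes have >= 2 live members:
    # equivalently, at most one internal vertex mixes first-marker alleles
    first_bits <- vapply(seq_along(tr$lat), function(v)
      sarg:::vertex_bit(tr, v, 1L), integer(1))
    mixed <- 0L
    for (v in which(tr$kind == sarg:::KIND_COAL)) {
      kids <- tr$e_child[tr$down[[v]]]
      leaves_below <- function(x) {
        if (tr$kind[x] == sarg:::KIND_LEAF) return(x)
        unlist(lapply(tr$e_child[tr$down[[x]]], leaves_below))
      }
      alle <- unique(first_bits[leaves_below(v)])
      if (length(alle) == 2L) mixed <- mixed + 1L
    }
    # both classes aggregate fully before the single cross-class join,
    # which is therefore the root: exactly one mixed vertex
    expect_identical(mixed, 1L)
  }
})

test_that("tree height matches the sum of exponential rates", {
  set.seed(111)
  sim <- sim_fixture(n = 10, seed = 77)
  reps <- 400
  h <- replicate(reps, {
    tr <- build_tree(sim$sample, tree_config(metric = metric("hamming", c0 = 0)))
    tr$lat[tr$root]
  })
  expected <- sum(1 / (2:10))
  expect_lt(abs(mean(h) - expected), 4 * sd(h) / sqrt(reps))
})

test_that("log-density categorical terms are exact for flat weights", {
  # c0 = 0 makes all pairing weights equal: each categorical term is
  # -log(#candidates); subtracting the exponential terms must leave
  # exactly -sum(log(k - 1)) for k = n..2
  sim <- sim_fixture(n = 6, seed = 5)
  tr <- build_tree(sim$sample, tree_config(metric = metric("hamming", c0 = 0),
                                           seed = 9))
  lats <- sort(tr$lat[tr$kind != sarg:::KIND_LEAF])
  dts <- diff(c(0, lats))
  exp_terms <- sum(dexp(dts, rate = 6:2, log = TRUE))
  expect_equal(tree_log_density(tr) - exp_terms, -sum(log(5:1)))
  expect_error(tree_log_density(structure(list(), class = "arg")),
               "build_tree")
})

test_that("partner selection frequencies match the exact categorical law", {
  # n = 3 so the partner of the drawn vertex is a single categorical draw;
  # enumerate the exact probabilities from the weights and compare
  m <- rbind(c(1, 1, 0, 0), c(1, 0, 0, 0), c(0, 0, 1, 1))
  sam <- arg_sample(m, c(5, 10, 15, 20), 100, Ne = 1e4, mu_prime = 2.5e-7)
  mu <- sam$mu
  met <- metric("hamming", c0 = 1)
  d12 <- hamming_distance(sam$haplotypes[[1]], sam$haplotypes[[2]])
  d13 <- hamming_distance(sam$haplotypes[[1]], sam$haplotypes[[3]])
  d23 <- hamming_distance(sam$haplotypes[[2]], sam$haplotypes[[3]])
  w <- function(d) exp(coal_log_weight(d, mu))
  set.seed(112)
  first_pair <- replicate(4000, {
    tr <- build_tree(sam, tree_config(metric = met))
    v <- which(tr$kind == sarg:::KIND_COAL)[1]
    paste(sort(tr$e_child[tr$down[[v]]]), collapse = "-")
  })
  # P(pair {a,b} coalesces first) = (1/3) sum over anchors of categorical
  p12 <- (w(d12) / (w(d12) + w(d13)) + w(d12) / (w(d12) + w(d23))) / 3
  p13 <- (w(d13) / (w(d12) + w(d13)) + w(d13) / (w(d13) + w(d23))) / 3
  p23 <- 1 - p12 - p13
  obs <- table(factor(first_pair, levels = c("1-2", "1-3", "2-3")))
  ct <- suppressWarnings(chisq.test(obs, p = c(p12, p13, p23)))
  expect_gt(ct$p.value, 1e-4)
})
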