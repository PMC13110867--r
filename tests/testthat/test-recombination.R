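test_that("event classification covers all five types", {
  mat <- rbind(c(1, 0), c(0, 1))
  g <- build_manual_tree(mat, c(2, 8), 20, list(1, 2))
  e <- g$up[[1]][1]
  g$e_anc[[e]] <- iset(0, 10)
  expect_identical(classify_event(g, e, 5), 1L)
  g$e_anc[[e]] <- iset(c(0, 6), c(4, 10))
  expect_identical(classify_event(g, e, 5), 2L)
  g$e_anc[[e]] <- iset(0, 4)
  expect_identical(classify_event(g, e, 5), 3L)
  expect_identical(classify_event(g, e, 0), 4L)
  g$e_anc[[e]] <- iset_empty()
  expect_identical(classify_event(g, e, 5), 5L)
})

test_that("unrestricted events choose edges by length and avoid types 3-5", {
  sim <- sim_fixture(n = 5, seed = 29)
  tr <- build_tree(sim$sample, tree_config(seed = 7))
  es <- sarg:::active_edges(tr)
  spans <- vapply(es, function(e) sarg:::edge_span(tr, e), numeric(1))
  set.seed(116)
  draws <- replicate(4000, sample_unrestricted_rr(tr)$e_r)
  obs <- table(factor(draws, levels = es))
  ct <- suppressWarnings(chisq.test(obs, p = spans / sum(spans)))
  expect_gt(ct$p.value, 1e-4)

  # recombination latitude is Beta(2,2)-scaled: mean at the edge midpoint
  e_big <- es[which.max(spans)]
  lr <- replicate(3000, {
    repeat {
      ev <- sample_unrestricted_rr(tr)
      if (ev$e_r == e_big) return(ev$l_r)
    }
  })
  mid <- mean(c(tr$lat[tr$e_child[e_big]], tr$lat[tr$e_parent[e_big]]))
  expect_lt(abs(mean(lr) - mid), 4 * sd(lr) / sqrt(length(lr)))

  # on a graph with interval gaps, breakpoints stay in the closure
  g <- sarg:::g_copy(tr)
  for (e in sarg:::active_edges(g)) {
    anc <- unclass(g$e_anc[[e]])
    if (length(anc) == 2L && anc[2] - anc[1] > 2000)
      g$e_anc[[e]] <- iset(c(anc[1], anc[1] + (anc[2] - anc[1]) * 0.6),
                           c(anc[1] + (anc[2] - anc[1]) * 0.4, anc[2]))
  }
  set.seed(117)
  types <- replicate(3000, {
    ev <- sample_unrestricted_rr(g)
    classify_event(g, ev$e_r, ev$bprime)
  })
  expect_true(all(types %in% c(1L, 2L)))
  expect_true(any(types == 2L))   # gaps make type 2 reachable
})

test_that("applying an unrestricted event preserves the counting invariant", {
  sim <- sim_fixture(n = 6, seed = 31)
  tr <- build_tree(sim$sample, tree_config(seed = 9))
  set.seed(118)
  g <- sarg:::g_copy(tr)
  for (i in 1:5) {
    ev <- sample_unrestricted_rr(g)
    apply_rr(g, ev)
    expect_identical(sum(g$kind == sarg:::KIND_COAL),
                     sum(g$kind == sarg:::KIND_RECOMB) + 6L - 1L)
  }
  expect_true(validate_genealogy(g, grid = 10)$structural_ok)
})

test_that("above-root recoalescence promotes a fresh grand MRCA", {
  sim <- sim_fixture(n = 4, seed = 37)
  tr <- build_tree(sim$sample, tree_config(seed = 10))
  old_root <- tr$root
  e_r <- sarg:::active_edges(tr)[1]
  lo <- tr$lat[tr$e_child[e_r]]; hi <- tr$lat[tr$e_parent[e_r]]
  ev <- list(e_r = e_r, bprime = sum(unclass(iset_closure(tr$e_anc[[e_r]]))) / 2,
             l_r = (lo + hi) / 2, e_c = NA_integer_,
             l_c = tr$lat[old_root] + 0.5, kind = "unrestricted")
  apply_rr(tr, ev)
  expect_false(tr$root == old_root)
  expect_identical(tr$kind[tr$root], sarg:::KIND_COAL)
  expect_identical(length(tr$up[[old_root]]), 1L)   # old root gained a parent
  expect_true(validate_genealogy(tr, grid = 5)$structural_ok)
})

test_that("breakpoint bounds extend exactly as far as the conditions allow", {
  # identical lineages left of the focal marker: bound reaches 0
  mat <- rbind(c(1, 1, 1), c(1, 1, 1), c(0, 0, 1), c(1, 0, 0))
  g <- build_manual_tree(mat, c(100, 200, 300), 1000,
                         list(list(1, 2), list(3, 4)))
  e1 <- g$up[[1]][1]; e2 <- g$up[[2]][1]
  expect_identical(breakpoint_lower_bound(g, 3L, e1, e2), 0)
  # differing lineages: bound stays at the previous marker
  e3 <- g$up[[3]][1]
  expect_equal(breakpoint_lower_bound(g, 3L, e1, e3), 200)
})

test_that("breakpoints are uniform on their support and strictly left of m", {
  set.seed(119)
  b <- replicate(5000, sample_breakpoint(2, 10))
  expect_true(all(b > 2 & b < 10))
  ks <- suppressWarnings(ks.test(b, "punif", 2, 10))
  expect_gt(ks$p.value, 1e-4)
  expect_error(sample_breakpoint(5, 5), "empty")
})

test_that("derived candidates are the mutation edges on a plain tree and each use reduces the count", {
  mat <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  g <- build_manual_tree(mat, c(10, 20), 100, list(list(1, 2), list(3, 4)))
  res <- next_inconsistent(g, 2L)
  M <- res$mutation_edges
  dc <- derived_candidates(g, M, 2L)
  expect_setequal(dc$edge, M)
  expect_equal(dc$weight, vapply(dc$edge, function(e) sarg:::edge_span(g, e),
                                 numeric(1)))
  # applying a derived event on each candidate reduces the count by one
  for (e_r in dc$edge) {
    g2 <- sarg:::g_copy(g)
    other <- setdiff(M, e_r)
    lo <- g2$lat[g2$e_child[e_r]]
    l_r <- lo + 0.1 * sarg:::edge_span(g2, e_r)
    l_c <- max(l_r, g2$lat[g2$e_child[other]]) + 0.05
    ev <- list(e_r = e_r, bprime = 15, l_r = l_r, e_c = other, l_c = l_c,
               kind = "derived")
    apply_rr(g2, ev)
    expect_identical(length(sarg:::count_mutations_at(g2, 2L)), 1L)
  }
})

test_that("wild candidates require a mutation brother and uncle; propagation removes two mutations", {
  # leaves: W=0, B=1 cherry; uncle U=1; X=1 above; Z=0 outermost.
  # marker has three mutation edges (B, U, X); a wild event on W that
  # recoalesces onto Z's lineage merges them into one.
  mat <- cbind(c(0, 1, 1, 1, 0))
  g <- build_manual_tree(mat, 50, 100,
                         list(list(list(list(1, 2), 3), 4), 5))
  M <- sarg:::count_mutations_at(g, 1L)
  expect_identical(length(M), 3L)
  wc <- wild_candidates(g, M, 1L)
  # W qualifies, and so does the wild cherry root below the same uncles
  expect_setequal(wc$edge, c(g$up[[1]][1], g$up[[6]][1]))
  # no qualifying configuration: a sample whose wild leaves lack mutation uncles
  mat2 <- rbind(c(1, 1), c(1, 0), c(0, 1), c(0, 0))
  g2 <- build_manual_tree(mat2, c(10, 20), 100, list(list(1, 2), list(3, 4)))
  M2 <- sarg:::count_mutations_at(g2, 2L)
  expect_identical(nrow(wild_candidates(g2, M2, 2L)), 0L)
  # apply the wild event: W detaches and recoalesces onto Z's edge
  e_r <- g$up[[1]][1]
  e_c <- g$up[[5]][1]
  l_r <- 0.1
  ev <- list(e_r = e_r, bprime = 20, l_r = l_r, e_c = e_c,
             l_c = g$lat[g$e_parent[e_c]] - 0.05, kind = "wild")
  apply_rr(g, ev)
  expect_identical(length(sarg:::count_mutations_at(g, 1L)), 1L)
})

test_that("derived recoalescence picks edges by admissible length", {
  # fabricate a minimal genealogy surface: two candidate edges with
  # admissible lengths 1 and 3 above l_r = 0
  g <- new.env()
  g$lat <- c(0, 0, 1, 3)
  g$e_child <- c(1L, 2L); g$e_parent <- c(3L, 4L)
  set.seed(120)
  picks <- replicate(4000, sample_derived_recoalescence(g, 0, c(1L, 2L))$e_c)
  p2 <- mean(picks == 2L)
  expect_lt(abs(p2 - 0.75), 4 * sqrt(0.75 * 0.25 / 4000))
  ls <- replicate(200, sample_derived_recoalescence(g, 0.5, c(1L, 2L))$l_c)
  expect_true(all(ls > 0.5))
  expect_null(sample_derived_recoalescence(g, 5, c(1L, 2L)))
})

test_that("wild recoalescence latitudes follow the inhomogeneous process", {
  # homogeneous limit: k parallel unit-rate branches over a tall interval
  k <- 3
  g <- new.env()
  g$lat <- c(rep(0, k), rep(60, k), 60)
  g$e_child <- seq_len(k); g$e_parent <- k + seq_len(k)
  g$root <- 2L * k + 1L
  set.seed(121)
  draws <- replicate(3000, sample_wild_recoalescence_latitude(g, 0, seq_len(k),
                                                             grid_size = 400L))
  ks <- suppressWarnings(ks.test(draws[draws < 50], "pexp", rate = k))
  expect_gt(ks$p.value, 1e-4)
  # refinement: grid 25 vs 500 agree in distribution
  set.seed(122)
  d25 <- replicate(2000, sample_wild_recoalescence_latitude(g, 0, seq_len(k),
                                                            grid_size = 25L))
  set.seed(123)
  d500 <- replicate(2000, sample_wild_recoalescence_latitude(g, 0, seq_len(k),
                                                             grid_size = 500L))
  ks2 <- suppressWarnings(ks.test(d25, d500))
  expect_gt(ks2$p.value, 1e-4)
  # above the root the intensity is bounded below, so the draw is finite
  expect_true(all(is.finite(replicate(200,
    sample_wild_recoalescence_latitude(g, 59.99, seq_len(k))))))
})

test_that("multiple-crossover mask algebra reproduces the worked identities", {
  # initial masks for a breakpoint at 3; a further crossover at 7 on the
  # tail-owning side, then another at 9
  ml <- iset(0, 3); mr <- sarg:::iset_raw(c(3, Inf))
  u1 <- mco_masks(mr, ml, 7)
  expect_identical(unclass(u1$other_side), c(0, 3, 7, Inf))   # [0,3) U [7,Inf)
  expect_identical(unclass(u1$tail_side), c(3, 7))            # [3,7)
  u2 <- mco_masks(u1$other_side, u1$tail_side, 9)
  expect_identical(unclass(u2$tail_side), c(0, 3, 7, 9))      # [0,3) U [7,9)
  expect_identical(unclass(u2$other_side), c(3, 7, 9, Inf))   # [3,7) U [9,Inf)
  # masks always partition [0, Inf)
  for (u in list(u1, u2)) {
    expect_identical(unclass(iset_union(u$tail_side, u$other_side)), c(0, Inf))
    expect_true(iset_is_empty(iset_intersect(u$tail_side, u$other_side)))
  }
})

test_that("the Markov window filter keeps exactly the overlapping edges", {
  mat <- rbind(c(1, 0), c(0, 1))
  g <- build_manual_tree(mat, c(2, 18), 20, list(1, 2))
  e <- g$up[[1]][1]
  g$e_anc[[e]] <- iset(0, 5)
  expect_identical(window_filter(g, e, 10, Inf), e)
  expect_identical(window_filter(g, e, 10, 2), integer(0))  # [8,12] misses [0,5)
  expect_identical(window_filter(g, e, 6, 2), e)            # [4,8] overlaps
  expect_identical(window_filter(g, e, 4.999, 0), e)        # contains p
  expect_identical(window_filter(g, e, 5, 0), integer(0))   # half-open end
})

test_that("constrained events strictly reduce the focal marker count", {
  set.seed(123)
  for (i in 1:8) {
    sim <- sim_fixture(n = 7, seed = 600 + i, rho = 4e-8, mu_prime = 3e-8)
    if (sim$sample$s < 2) next
    g <- build_tree(sim$sample, tree_config(seed = i))
    cfg <- sweep_config()
    scan <- next_inconsistent(g, 1L)
    while (!is.null(scan)) {
      m <- scan$marker_index
      M <- scan$mutation_edges
      count <- length(M)
      while (count >= 2L) {
        sarg:::constrained_event(g, m, M, cfg)
        M2 <- sarg:::count_mutations_at(g, m)
        expect_lt(length(M2), count)
        count <- length(M2); M <- M2
      }
      if (m >= sim$sample$s) break
      scan <- next_inconsistent(g, m + 1L)
    }
  }
})
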