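test_that("marginal trees of a plain tree are the tree itself", {
  sim <- sim_fixture(n = 6, seed = 17)
  tr <- build_tree(sim$sample, tree_config(seed = 4))
  ref <- marginal_tree(tr, 1)
  for (p in c(100, 5000, 9999)) {
    mt <- marginal_tree(tr, p)
    expect_identical(mt$cvert, ref$cvert)
    expect_identical(mt$cparent, ref$cparent)
    # leaf set is always the full sample
    expect_true(all(which(tr$kind == sarg:::KIND_LEAF) %in% mt$cvert))
  }
})

test_that("one recombination changes marginal trees only right of the breakpoint", {
  mat <- rbind(c(1, 0), c(1, 1), c(0, 1), c(0, 0))
  g <- build_manual_tree(mat, c(100, 900), 1000,
                         list(list(1, 2), list(3, 4)))
  # detach leaf 3's lineage for [500, Inf) and recoalesce onto leaf 1's edge
  e_r <- g$up[[3]][1]
  e_c <- g$up[[1]][1]
  ev <- list(e_r = e_r, bprime = 500, l_r = 0.1, e_c = e_c, l_c = 0.2,
             kind = "unrestricted")
  apply_rr(g, ev)
  expect_identical(sum(g$kind == sarg:::KIND_COAL),
                   sum(g$kind == sarg:::KIND_RECOMB) + 4L - 1L)
  left <- marginal_tree(g, 100)
  right <- marginal_tree(g, 900)
  # left of the breakpoint: original cherries; right: leaf 3 moved next to 1
  sib <- function(mt, a, b) mt$cparent[a] == mt$cparent[b]
  expect_true(sib(left, 3L, 4L))
  expect_false(sib(right, 3L, 4L))
  expect_true(sib(right, 1L, 3L))
  v <- validate_genealogy(g, grid = 10)
  expect_true(v$structural_ok)
})

test_that("four-gamete violations are inconsistent under every topology", {
  mat <- rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1))
  for (topo in all_topologies_4()) {
    g <- build_manual_tree(mat, c(100, 200), 1000, topo)
    cons <- is_consistent(g)
    expect_false(as.logical(cons))
    expect_true(any(attr(cons, "mutation_counts") > 1L))
  }
})

test_that("single-marker samples are consistent under the infinite left bias", {
  sam <- arg_sample(matrix(c(0, 0, 1, 1, 1), ncol = 1), 50, 100)
  tr <- build_tree(sam, tree_config(metric = metric("left", c0 = Inf), seed = 6))
  expect_true(as.logical(is_consistent(tr)))
})

test_that("validate reports structural damage distinctly from inconsistency", {
  sim <- sim_fixture(n = 5, seed = 19)
  tr <- build_tree(sim$sample, tree_config(seed = 5))
  v0 <- validate_genealogy(tr)
  expect_true(v0$structural_ok)
  # corrupt a latitude: parent below child
  g2 <- sarg:::g_copy(tr)
  root_kid <- g2$e_child[g2$down[[g2$root]][1]]
  g2$lat[g2$root] <- g2$lat[root_kid] - 0.01
  v <- validate_genealogy(g2)
  expect_false(v$structural_ok)
  expect_true(any(grepl("span|latitude", v$messages)))
})

test_that("genealogy statistics: closed forms and the positionwise oracle", {
  # n = 2: diversity = 2 * coalescence latitude
  sam <- arg_sample(rbind(c(1, 0), c(0, 1)), c(10, 20), 100)
  tr <- build_tree(sam, tree_config(seed = 8))
  st <- genealogy_stats(tr)
  expect_identical(st$n_recombinations, 0L)
  expect_equal(st$diversity, 2 * tr$lat[tr$root])
  expect_equal(st$tree_height, tr$lat[tr$root])

  # 3 leaves, 1 recombination: integrate pairwise TMRCA on a fine grid
  mat <- rbind(c(1, 0), c(0, 1), c(1, 1))
  g <- build_manual_tree(mat, c(100, 900), 1000, list(list(1, 2), 3))
  ev <- list(e_r = g$up[[1]][1], bprime = 400, l_r = 0.2,
             e_c = g$up[[3]][1], l_c = 0.5, kind = "unrestricted")
  apply_rr(g, ev)
  st2 <- genealogy_stats(g)
  expect_identical(st2$n_recombinations, 1L)
  grid <- seq(0.5, 999.5, by = 1)
  oracle <- mean(vapply(grid, function(p) {
    tm <- sarg:::pairwise_tmrca(g, p)
    mean(2 * tm[upper.tri(tm)])
  }, numeric(1)))
  expect_equal(st2$diversity, oracle, tolerance = 1e-3)
})

test_that("marginal phylogenies convert to valid ape trees", {
  sim <- sim_fixture(n = 7, seed = 23)
  a <- infer_arg(sim$sample, seed = 2)
  phy <- marginal_phylo(a, sim$sample$positions[1])
  expect_s3_class(phy, "phylo")
  expect_identical(ape::Ntip(phy), 7L)
  expect_true(ape::is.binary(phy))
  expect_true(ape::is.rooted(phy))
})
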