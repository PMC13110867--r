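# Fixtures and independent oracles shared across the suite. Everything is
# generated in code; nothing is read from disk except the bundled
# synthetic text sample.

# the minimal four-gamete violation: both markers see all four gametes
four_gamete_sample <- function() {
  arg_sample(rbind(c(0, 0), c(0, 1), c(1, 0), c(1, 1)),
             positions = c(100, 200), seq_length = 1000)
}

sim_fixture <- function(n = 8, seq_length = 1e4, mu_prime = 2e-8, rho = 2e-8,
                        seed = 1, Ne = 1e4) {
  simulate_sample(sim_spec(n = n, seq_length = seq_length, Ne = Ne,
                           mu_prime = mu_prime, rho = rho, seed = seed))
}

adh_fixture <- function() {
  read_sample_text(system.file("extdata", "adh_synthetic.tsv", package = "sarg"),
                   Ne = 1720600, mu_prime = 5.49e-9)
}

# bit-by-bit Hamming distance: the naive oracle
naive_hamming <- function(a, b) sum(as_bits(a) != as_bits(b))

# dense boolean-grid oracle for interval algebra on integer endpoints:
# evaluate membership on a half-unit grid over [0, hi)
grid_points <- function(hi) seq(0.25, hi - 0.25, by = 0.5)
iset_from_membership <- function(member, pts) {
  # reconstruct the canonical interval set from grid membership (grid step
  # 0.5, integer endpoints)
  if (!any(member)) return(iset_empty())
  r <- rle(member)
  ends <- cumsum(r$lengths)
  starts <- c(1, utils::head(ends, -1) + 1)
  keep <- r$values
  iset(pts[starts[keep]] - 0.25, pts[ends[keep]] + 0.25)
}
random_iset <- function(hi = 20L, k = 3L) {
  pts <- sort(sample(0:hi, 2L * k, replace = TRUE))
  iset(pts[c(TRUE, FALSE)], pts[c(FALSE, TRUE)])
}

# naive per-marker mutation-edge recount over the whole genealogy: the
# reference the MMN scanner is checked against
naive_first_inconsistent <- function(g, from = 1L) {
  for (k in from:g$sample$s) {
    hits <- sarg:::count_mutations_at(g, k)
    if (length(hits) >= 2L) {
      return(list(marker_index = k, mutation_edges = hits))
    }
  }
  NULL
}

# hand-built genealogy: a caterpillar / balanced tree over the given
# 0/1 haplotype rows, with unit-ish latitudes; topology is a list of
# nested pairs, e.g. list(list(1, 2), list(3, 4))
build_manual_tree <- function(mat, positions, seq_length, topology,
                              step = 0.35) {
  sam <- arg_sample(mat, positions, seq_length)
  g <- sarg:::g_new(sam)
  full <- sarg:::iset_raw(c(0, seq_length))
  depth <- 0
  build <- function(node) {
    if (!is.list(node)) return(as.integer(node))
    l <- build(node[[1L]]); r <- build(node[[2L]])
    depth <<- depth + step
    v <- sarg:::g_add_vertex(g, depth, sarg:::KIND_COAL,
                             seq_and(g$hap[[l]], g$hap[[r]]))
    sarg:::g_add_edge(g, l, v, full)
    sarg:::g_add_edge(g, r, v, full)
    v
  }
  g$root <- build(topology)
  g
}

# all rooted binary tree topologies over leaf labels 1..4 (15 of them)
all_topologies_4 <- function() {
  out <- list()
  leaves <- 1:4
  pairs3 <- function(x) list(c(x[1], x[2]), c(x[1], x[3]), c(x[2], x[3]))
  # shape A: ((a,b),(c,d)) -- 3 distinct
  part2 <- list(c(1, 2), c(1, 3), c(1, 4))
  for (p in part2) {
    q <- setdiff(leaves, p)
    out[[length(out) + 1L]] <- list(list(p[1], p[2]), list(q[1], q[2]))
  }
  # shape B: (((a,b),c),d) -- 4 choices of d x 3 pairs = 12
  for (d in leaves) {
    rest <- setdiff(leaves, d)
    for (pr in pairs3(rest)) {
      c3 <- setdiff(rest, pr)
      out[[length(out) + 1L]] <-
        list(list(list(pr[1], pr[2]), c3), d)
    }
  }
  out
}
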