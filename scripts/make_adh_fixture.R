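#!/usr/bin/env Rscript
# Generates the bundled synthetic Adh-like fixture:
# 11 haplotypes x 43 segregating sites simulated by the package's own
# Hudson coalescent-with-recombination under stdpopsim-style
# D. melanogaster parameters (mu' = 5.49e-9 per bp per generation,
# Ne = 1,720,600, crossover rate 8.4e-9), locus length chosen so the
# expected number of segregating sites is ~43; the first seed yielding
# exactly 43 sites is kept. This is a synthetic stand-in with the same
# dimensions as a classic 11 x 43 Adh data set, not real data.
library(sarg)
l <- 400; Ne <- 1720600; mu <- 5.49e-9; rho <- 8.4e-9
for (seed in 1:1000) {
  sim <- simulate_sample(sim_spec(n = 11, seq_length = l, Ne = Ne,
                                  mu_prime = mu, rho = rho, seed = seed))
  if (sim$sample$s == 43L) {
    cat("seed", seed, "gives 43 segregating sites; HK Rmin =",
        hudson_kaplan_rmin(sim$sample), "\n")
    write_sample_text(sim$sample, "inst/extdata/adh_synthetic.tsv")
    break
  }
}
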