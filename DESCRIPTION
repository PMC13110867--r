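Package: sarg
Title: Sample-Consistent Ancestral Recombination Graph Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Model-based inference of ancestral recombination graphs (ARGs)
    that are consistent with a sample of phased, polarized biallelic
    haplotypes under the infinite-sites model. An initial coalescent tree is
    built under a haplotype pseudometric with Gumbel-max or secretary
    partner sampling, then a left-to-right sweep adds constrained
    recombination-and-recoalescence events until every marker carries at
    most one mutation in its marginal tree. Includes bit-packed haplotype
    arithmetic over GF(2), a chunked minimum-mutation-number scanner,
    hash-gated upstream updates, an optional Markov window approximation, a
    built-in Hudson coalescent-with-recombination simulator for fixtures,
    phased-VCF input, and tree-sequence table export.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    graphics,
    ape,
    jsonlite,
    optparse,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
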