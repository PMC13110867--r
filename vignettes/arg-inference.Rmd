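---
title: "Sample-consistent ARG inference: model, algorithms and design notes"
author: "sarg"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sample-consistent ARG inference: model, algorithms and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's own account of what it computes and why
the pieces look the way they do. It covers the probabilistic model, the
tunable parameters, the numerical choices, what the built-in simulator
does and does not emulate, and the design decisions taken where the
method left genuine latitude.

## The model

A sample is a set of `n` phased, polarized haplotypes over `s` biallelic
markers with physical positions in `[0, l)`; allele 0 is ancestral
(wild), 1 derived. Haplotypes are bit-packed vectors over GF(2),
least-significant-bit first within bytes, so a byte holds an 8-marker
chunk; XOR flags markers with an odd number of mutations between two
sequences and AND is the no-back-mutation ancestor rule (an ancestor
carries the derived allele only if all descendants through ancestral
material do). The demography enters through the global mutation rate
`mu = 4 * Ne * mu_prime * l` for a diploid effective population size
`Ne` and per-bp, per-generation rate `mu_prime`.

A genealogy is a vertex/edge graph: leaves at latitude 0, coalescence
vertices with two children, recombination vertices with one child and
two parents partitioned by a *recombination mask* `{[0,b), [b,Inf)}` (or
a finite union after multiple crossovers). Each edge carries the
interval set of genomic material ancestral to the sample that flows
through it; a parental edge's set is its mask intersected with the union
of the child edges' sets. Restricting to edges ancestral at a position
and contracting pass-through vertices yields the marginal tree there. A
genealogy is *consistent* when every marker's marginal tree carries at
most one mutation edge (an edge whose endpoints differ at that marker) —
the infinite-sites criterion.

Latitudes are stored in coalescent units and scaled by `2 * Ne` only at
tree-sequence export, because every rate in the model (exponential
latitude increments, unit coalescence rate per edge) is naturally
expressed on that scale.

## Initial tree construction

Each coalescence event draws an anchor uniformly among live lineages and
a partner with probability proportional to `mu^d / Gamma(d + 1)`, the
unnormalized Poisson mass of the biased distance `d = c0 * d(h_a, h_b)`.
Two pseudometrics ship with the package: Hamming distance and the
left-marker distance (0/1 by first-marker agreement). They are
pseudometrics — distinct haplotypes may be at distance 0 — which is what
lets `c0 = Inf` with the left distance aggregate allele classes exactly
and produce a tree consistent for marker 1.

Weights spanning hundreds of orders of magnitude make normalization
hopeless, so selection uses the Gumbel-max trick: argmax of log-weights
plus iid standard Gumbel noise is a categorical draw needing no
normalizer. `log Gamma` is evaluated by the library `lgamma` — exact
rather than a truncated Stirling series, same asymptotics. For large
candidate sets, *secretary sampling* trades exactness for early
termination: all perturbations are generated, the first `ceiling(t0 *
m)` candidates are only observed, and the scheme stops at the first
later candidate exceeding the learning maximum (falling back to the full
argmax otherwise). This scheme reproduces both reference behaviours: the
early-termination probability is `1 - t0` and the probability of
returning the exact draw tends to `t0 * (1 - log t0)`. Candidates are
re-permuted freshly at every event, which the secretary analysis
requires. Latitude increments are exponential with rate equal to the
number of live vertices — that is the model, deliberately not the
`k(k-1)/2` of the standard coalescent, and the height property
`E[height] = sum_{k=2}^{n} 1/k` is what the tests check.

Degenerate bias (`c0 = Inf`) can leave an anchor with no positive-weight
partner even though other pairs have one; the builder then redraws the
anchor among vertices that do, and only when *no* pair anywhere has
positive weight does it coalesce a uniform pair. This keeps
finite-weight classes aggregating first and makes the flagship
left-distance behaviour (classes merge internally before the single
cross-class join) hold by construction.

The density of the resulting tree is accumulated on the log scale: per
event, the chosen partner's log-weight minus the log-sum-exp of the
weights actually traversed, plus the exponential latitude terms. With
`t0 = 1` all candidates are traversed, so the normalizer is the full
sum; with `t0 < 1` it is the traversed prefix.

## The consistency sweep

Inference walks markers left to right. The minimum-mutation-number
scanner processes markers in 8-marker chunks aligned with the packed
bytes: per chunk, every edge contributes `(h_parent XOR h_child) AND
m_omega` computed on whole bytes across all edges at once, where the
mask zeroes markers outside both the scan window and the edge's
ancestral material. Traversal is bottom-up by child latitude, skipping
edges whose child byte is all-wild on the live markers (0 is absorbing
for AND, so nothing above can mutate along that line). Chunk width is a
package option (`sarg.chunk`); results are invariant to it, and the
test-suite checks widths 1, 8 and 64 agree.

At an inconsistent marker the engine pools three kinds of
mutation-reducing events and draws among candidate edges purely by
branch length (no priority among kinds — the aim is closeness to the
coalescent-with-recombination, not maximal local reduction):

* **Derived events**: the recombination sits on a mutation edge or any
  edge of its downstream chain of marginally sibling-less edges;
  detaching that derived material and recoalescing it where it meets
  derived material removes exactly one mutation.
* **Wild events**: admissible when the wild chain's marginal brother and
  uncle are both mutation edges; the detachment flips the brother's
  junction to derived and the flip cascades upward through consecutive
  derived uncles, so one event can remove several mutations.
* **Multiple crossovers**: when the drawn edge is the parental edge of
  an existing recombination vertex owning the rightmost mask portion,
  the same effect is achieved by mask editing (intersect the tail side
  with `[0, b')`, give the other side `[b', Inf)`) with no new vertices.

Recoalescence admissibility is decided by the allele the reattached
lineage would first meet: the child allele for an edge ancestral at the
marker, otherwise the allele of the first ancestral vertex upstream of
the insertion point. This admits non-ancestral edges that lead into the
right material. Two exclusion sets keep the reduction guarantees exact:
the vanishing chain pieces above the recombination (their material
leaves with the lineage), and — for wild events — the *flip path*: the
junctions meant to flip and the pass-through vertices between them,
where re-inserting wild material would break the merge. Derived
recoalescence picks an edge proportional to its admissible length
(clipped below the recombination latitude) with a Beta(2,2)-scaled
location; wild recoalescence draws its latitude from the inhomogeneous
Poisson process whose intensity is the number of admissible branches,
inverted on a logarithmic quadrature grid (default 25 nodes, option
`sarg.grid`) with constant rate 1 above the grand MRCA, where
recoalescence promotes a fresh root. Event locations on branches use the
Beta(2,2) location-scale family rather than the uniform law; the
symmetry is preserved while the mass moves away from branch endpoints,
which prevents the accumulation of numerically hazardous short branches
as the graph grows.

Breakpoints are uniform on `[b_lo, m)` where the lower bound extends
left of the previous marker exactly as far as, for every intervening
marker, (i) the recombination edge carries no material there, or (ii)
the recoalescence edge carries material and the two lineages agree, or
(iii) neither does and the first ancestral vertex upstream of the
insertion point matches the lineage. Condition (ii) is meaningful only
when the recoalescence edge is ancestral at the marker — an agreement
test against a non-ancestral edge would compare against an arbitrary
value while the material actually merges further upstream — so the
conditions are evaluated in that order. The bound is additionally
clipped so material remains on the left of the breakpoint, discarding
would-be type 4 events (material only right). The uniform law over the
admissible support was chosen over a truncated exponential: it keeps all
admissible type 2 positions (breakpoints in non-ancestral gaps of the
closure) reachable and avoids numerically fragile inverse transforms.

Every constrained event must strictly reduce the focal marker's
mutation count — this is asserted after each event and bounds the sweep
(`|M| - 1` events per marker at most), and the breakpoint bound
guarantees processed markers never regain inconsistency. Proposals that
find no admissible partner are rejected and redrawn; after 50 rejections
the engine switches to guided proposals that keep only candidate rows
with provably nonempty recoalescence support and truncate the location
below the highest admissible partner. The pairwise structure of derived
chains guarantees at least one such row exists, so termination is not
left to luck in the rare geometries (one derived chain entirely above
the other) where plain rejection could stall. Multiple-crossover
attempts are verified on a scratch copy (strict decrease at the focal
marker, no increase in `[b', m)`) before being committed; the conditions
are restrictive and the package makes no attempt to bias toward them.

The Markov window (`sweep_config(window = w)`) drops any edge whose
ancestral material misses `[p - w, p + w]` from both the candidate and
recoalescence sets, including the rate of the wild latitude process;
`w = 0` confines everything to the current marginal tree (an SMC-like
first-order scheme) and `w = Inf` disables the approximation. The filter
is applied only below the root; the above-root regime stays available
regardless, so wild events always have an escape latitude. Narrower
windows forgo distant, more parsimonious recoalescence partners, which
is why recombination counts tend to rise as `w` shrinks — the
acceptance suite checks the direction of that effect, not a number.

## Graph maintenance

After an event, haplotypes (masked AND of children) and ancestral
intervals (mask intersected with the children's union) upstream of the
modified edges are recomputed children-first by latitude. Propagation
along an edge stops when the 64-bit NH-family universal hash of its
(child haplotype, interval set) state is unchanged — coalescences with
untouched lineages stop the spread well below the root. The hash key is
drawn from the run's RNG, so a collision (probability at most `2^-64`
per pair) would at least be reproducible; `validate_genealogy()` is the
final safety net, and the test-suite checks gated and full recomputation
agree event by event. Position-to-index lookups — needed constantly for
masking — use interpolation-sequential search seeded by a least-squares
fit of index on position over all `s` markers, computed once per sample
(positions never change over a genealogy's lifetime); the empty case
returns the sentinel index 0.

Equal latitudes cannot arise from the continuous draws; locations are
nevertheless clamped strictly inside open supports with a relative
margin of `1e-9` of the span, so degenerate arithmetic cannot produce
zero-length edges.

## The built-in simulator

`simulate_sample()` is a Hudson-style backward coalescent with
recombination: pairwise coalescence at rate 1 (time in `2 Ne`
generations), per-lineage recombination at rate `R/2` scaled by the
physical span of its material, breakpoints uniform on the span, material
trimmed at each segment's local MRCA, and infinite-sites mutations laid
on the recorded node/edge tables at rate `theta/2` per unit branch
length. Its calibration is itself tested (Watterson's `E[S] = theta
H_{n-1}`, pairwise diversity `theta`). It emulates a neutral,
panmictic, constant-size population with uniform rates; it does not
emulate selection, structure, gene conversion, mutation-rate
heterogeneity, genotyping error or missing data — so green tests say
the inference machinery is correct under the neutral model, not that
real data meet its assumptions. Note the simulator follows the standard
coalescent (`k(k-1)/2`) while the tree *builder* uses rate `#live`; the
two are different models by design, and the height test targets the
builder's.

## Bundled data and problem sizes

`inst/extdata/adh_synthetic.tsv` is a synthetic stand-in with the
dimensions of the classic Adh data set (11 haplotypes, 43 segregating
sites): simulated by the package's own generator under stdpopsim-style
D. melanogaster parameters (`mu' = 5.49e-9`, `Ne = 1,720,600`, crossover
rate `8.4e-9`, 400 bp chosen so the expected number of segregating sites
is about 43), keeping the first seed that yielded exactly 43 sites. It
was conditioned only on those dimensions, never on downstream results,
and it is not real sequencing data — numbers computed from it
characterize the method, not the Adh locus.

Replicate counts were fixed once to keep the whole suite comfortably
inside an ordinary workstation run: 1,000 ARGs per metric in the
acceptance script's count experiment (120 per metric in the test
block), 200 fuzz validations, 200 matched window pairs in the tests (60
in the script), 2,000 tree heights, and `1e5`-draw categorical checks.
Statistical assertions use four-standard-error bands (or chi-squared /
Kolmogorov-Smirnov tests at `p > 1e-4`) so that false alarms are rare
without masking real defects.

## Known limitations

Markers must be biallelic, phased and polarized, with no missing data;
the recombination masks and GF(2) machinery would extend to simple
absorbing-state mutation models, but none of that is implemented.
The method samples *consistent* genealogies, not posterior draws: the
distribution is a restriction of the coalescent-with-recombination, and
densities are accumulated only for the initial tree. Runtime grows
quickly with sample size and marker count in this R implementation;
the Markov window is the intended relief valve for larger problems.
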