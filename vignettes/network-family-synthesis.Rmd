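---
title: "Synthesizing PPI network families: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesizing PPI network families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ppifam)
```

## The problem

Network alignment algorithms need benchmarks where the true node
correspondence is known. Real protein-protein interaction (PPI)
networks never come with a gold-standard alignment, so `ppifam`
synthesizes *families* of networks that share ancestry by construction:
an ancestral network is grown from a small seed, duplicated at every
internal node of a user-defined binary phylogeny, and each copy then
grows independently to its descendant's size. Because every node
carries its ancestral lineage, the functional-orthology (FO) groups of
the leaf networks are exact ground truth, and emulated BLAST-like
similarity scores give aligners the same kind of noisy cross-network
evidence they would see on real data.

## Growth models

All four models share one contract: *add one node and its edges to an
existing network*, never deleting previously added nodes. A step that
leaves the new node isolated (or, for DMC, would strand its anchor) is
discarded and redrawn — output networks are singleton-free. The retry
loop is capped (default 1,000) so pathological parameter sets fail with
an explicit error instead of spinning.

**DMC (duplication–mutation–complementation).** A uniformly chosen
anchor `u` is duplicated into `v`; for each shared neighbour, with
probability `q_mod` exactly one of the two parallel edges (chosen
equiprobably) is deleted; with probability `q_con` the complementary
edge `(u, v)` is added. Defaults `q_con = 0.5`, `q_mod = 0.4`. Because
the expected number of edges a new node brings is proportional to the
current mean degree times `2(1 - q_mod) > 1`, edge density grows
slowly with network size (roughly as `N^0.2` at the defaults), which
is what pushes 5,500-node networks toward realistic densities of
around ten edges per node.

**DMR (duplication with random mutation).** `v` copies the anchor's
edges, each copy is deleted independently with probability `q_del`,
and every other node gains an edge to `v` with probability `q_new / N`.
Defaults `q_new = 0.85`, `q_del = 0.4`.

**CG (crystal growth).** Each new node attaches exactly `delta = 4`
edges; the first target is uniform, subsequent targets are drawn from
the neighbourhood union of the targets chosen so far (falling back to a
uniform draw when that set is exhausted), which makes attachment
locally clustered. Edge count is deterministic:
`|E| = |E_seed| + delta * (N - N_seed)`.

**STICKY (incremental stickiness model).** Each new node receives an
*assigned degree* `d` drawn from a truncated discrete power law
`p(d) ∝ d^{-gamma_deg}` on `{1, …, d_max}` (defaults `gamma_deg = 1.6`,
`d_max = 50`; exact inverse-CDF sampling, no rejection). An edge to an
existing node `j` with assigned degree `d_j` is inserted with
probability `min(1, d * d_j / Σ d)` — the stickiness product rule, under
which a node's expected number of insertions matches its assigned
degree. After insertion, with probability `f_del = 0.55` one randomly
chosen edge of the new node is removed again. The new node then
inherits the biological function of one neighbour selected
proportionally to the neighbours' stickiness.

Two readings of the deletion step are defensible ("remove an edge …
with probability f_del"): removing *each* inserted edge independently,
or removing *one* randomly chosen edge. We implement the single-edge
reading: it preserves the sampled power-law shape of the degrees (the
per-edge reading thins every degree by `1 - f_del`, compressing the
degree range and visibly steepening the fitted exponent out of the
range observed in curated PPI databases), and it yields the denser,
more realistic networks of the two. The acceptance suite asserts that
fitted exponents of 5,500-node STICKY networks fall inside the
empirically observed band [1.53, 1.84].

A deliberately simple consequence of this architecture is that the
STICKY model's expected edge density is bounded by the mean assigned
degree (≈ 4.7 at the defaults): the model produces around six edges
per node at 5,500 nodes, noticeably sparser than the duplication
models. Users wanting denser stickiness networks should raise `d_max`
or lower `f_del`.

### Seed networks

Duplication dynamics are super-linear, so the seed's edge density
leaves a permanent imprint on the final density: a dense seed (for
example a clique grown by the model itself) inflates 5,500-node DMC/DMR
networks far past realistic densities. The default seed is therefore a
sparse connected graph — a ring over 50 nodes plus uniformly sampled
chords, 2.2 edges per node — the ancestral density consistent with the
benchmark-scale densities these models are tuned to produce (and with
the ~2 edges/node of earlier-generation duplication benchmarks). At
`seedSize = 5` the construction saturates to the 5-clique. Every seed
node founds its own FO group; users may substitute any network read
with `readEdgeList()`.

## Functional annotation and the null function

Each grown node records its anchor's *lineage* (the founding seed
node's group). Lineage is never erased: the annotation *label* is
dropped to the null function independently per node with probability
`1 - p_fo` (default `p_fo = 0.9`). Keeping lineage and label separate
matters: if a null label were itself heritable, null fractions would
compound along lineages and drift toward one in long simulations,
whereas a per-node dropout keeps the null fraction at an interpretable
`1 - p_fo` among grown nodes. Null-function nodes appear in no FO group
and therefore never count as orthologs.

## Cross-network similarity scores

Scores emulate BLAST bit scores. Every node gets a private scale
factor `λ_v ~ U(1 - λ_max, 1 + λ_max)` (`λ_max = 0.1`; symmetric,
mean-preserving jitter). Orthologous cross-network pairs score
`λ_u λ_v X` with `X ~ Γ(k_o = 0.94, θ_o = 169.49)`; non-orthologous
background pairs use `X ~ Γ(k_n = 0.86, θ_n = 42.00)`. How many
background pairs receive scores is governed by a per-node spurious
partner count drawn from a truncated power law with exponent
`beta_spur = 1.7` (the midpoint of the empirically observed 1.28-2.07
band for potential-ortholog counts) on `{0, …, l_max_spur = 10}`,
weighted as `(l + 1)^{-beta}` so that zero partners is the modal
outcome. This reproduces the heavy-tailed shape of per-node
potential-ortholog counts without emitting a quadratic number of score
records. `potentialOrthologCounts()` applies the standard bit-score
threshold (45) to recover those counts from a score table.

## Feature analyses

* **Degree exponent** — ordinary least squares on
  `log10(count) ~ log10(degree)` over degrees with positive counts
  (degree 0 excluded), unbinned and unweighted; exact on noiseless
  power-law histograms. This mirrors the simple polyfit-style procedure
  used in the PPI literature rather than more robust MLE estimators, so
  fitted values are comparable with published ones.
* **Clustering coefficient** — `2e / (k(k-1))`, defined as 0 for
  `k < 2` so distribution totals stay equal to the node count.
* **Graphlets** — the catalogue of all connected graphs on 2-5 nodes is
  built by exhaustive enumeration with brute-force isomorphism
  rejection over vertex permutations: 30 graphlets (the single edge
  plus the 29 classic multi-node graphlets) carrying 73 automorphism
  orbits. Orbit 0 is the edge endpoint, so its distribution reproduces
  the degree distribution. Numbering is deterministic (size, then edge
  count, then canonical encoding; orbits by degree and neighbour-degree
  profile) and internally consistent, which is all GDDA requires.
  Per-node orbit counts use ESU enumeration of connected induced
  subgraphs in compiled code; a brute-force all-subsets oracle verifies
  it on small graphs in the test suite.
* **GDDA** — per orbit, distributions are scaled by `1/k`, normalized
  to unit mass, compared with the scaled Euclidean distance
  `(1/√2)·‖N_a - N_b‖₂`, and the per-orbit agreements `1 - d_j` are
  averaged arithmetically over orbits where at least one network has
  mass. Orbits empty in both networks are skipped rather than scored as
  perfect agreement.
* **Gamma fits** — maximum likelihood via `fitdistrplus`, used both to
  validate emitted scores and as a user-facing analysis.

## Calibration

`gridSearch()` replicates the estimation protocol: equal-width 0.05
grids over the model's free parameters, a small number of replicate
networks per grid point (default 3), and a discrepancy that combines
exactly the four published criteria — relative edge-density difference,
Kolmogorov–Smirnov distances between degree and clustering-coefficient
distributions, and `1 - GDDA` when graphlet statistics are supplied —
with equal weights (the authors' weighting is not published; equal
weights degrade gracefully when the costly GDDA term is omitted). Ties
break to the lexicographically smallest parameter tuple. CG is excluded
from calibration by default: its single parameter is conventionally
held at `delta = 4`.

At the reduced problem size used in the tests (1,000-node networks,
3 replicates), `q_mod` is recovered essentially always, while `q_con`
is more weakly identified — its density footprint at 1,000 nodes is
small relative to replicate noise — so single trials occasionally land
two grid steps away on that axis. Recovery sharpens with network size
and replicate count.

## Benchmark suites

`presetTree()` ships three layouts: pairwise (3,000- and 4,000-node
leaves from a 2,000-node ancestor), 5-way (1,250/1,500/1,750/2,000/
2,000) and 8-way (eight leaves of 1,000). Only the pairwise ancestral
size is published; the 5-way and 8-way root sizes (1,000 and 500) and
internal sizes are package choices, taken as parent/child midpoints so
that divergence depth interpolates monotonically — leaf sizes, the
testable surface, are exact. The default full build is
3 suites × 4 models × 10 families = 120 families, 600 networks
(`planSuite()` enumerates it without generating anything). Per-family
seeds derive from the master seed by a counter scheme, so builds are
reproducible and families are independent.

## What the generator does and does not emulate

Synthetic families capture: scale-free-like degree distributions,
locally clustered attachment, density growth with proteome size,
ground-truth orthology with annotation dropout, and Gamma-shaped
similarity scores with heavy-tailed potential-ortholog counts. They do
not capture: hierarchical/multi-functional protein annotation,
interaction-pattern rewiring of multi-functional proteins,
experiment-specific ascertainment bias in interaction detection,
e-value filtering of alignments, or mixed growth mechanisms within one
lineage. Passing tests therefore demonstrate internal consistency with
the stated models and published summary statistics, not fidelity to any
particular organism's interactome.

## Numerical and testing choices

Randomness flows through R's global RNG; every exported entry point
takes an optional `seed` so whole families are reproducible, and all
serializations are canonically sorted so a fixed seed gives
byte-identical output. Scores are printed with six significant digits.
Degenerate inputs fail loudly: all-zero stickiness degrees, empty
summaries, non-positive Gamma samples, sub-minimum seeds.

Test problem sizes are chosen to keep the default suite fast while
preserving statistical power: density and exponent checks use ten
replicate 5,500-node networks per model; Gamma-recovery uses 10^5
scores; stochastic assertions use three-standard-error bands; the
grid-search recovery study uses 1,000-node networks with 3 replicates
per point over the 9 × 9 default window; GDDA comparisons use a
300-node dense static-stickiness surrogate as the common reference.

## Known limitations

* The STICKY density ceiling discussed above: at the default
  `gamma_deg`/`d_max` the model cannot reach the densities of the
  duplication models; this is a structural property of bounded assigned
  degrees.
* Graphlet counting is exhaustive over connected induced subgraphs of
  size ≤ 5; dense networks with large hubs make the subgraph count
  combinatorial (a degree-`h` hub alone contributes `choose(h, 4)`
  5-node stars). Practical up to a few thousand nodes at PPI-like
  densities.
* FO groups are founded only by seed nodes; lineage-specific gene
  families (groups born after a bifurcation) are not modelled, so
  every orthology group traces to the common ancestor.
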