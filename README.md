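# ppifam

Synthesis of protein–protein interaction (PPI) network **families** for
benchmarking network-alignment algorithms — with known ground-truth
orthology, emulated sequence-similarity scores, and the statistical
feature analyses needed to validate the synthetic networks against real
interactomes.

## Who this is for

Developers and evaluators of biological network alignment methods
(pairwise and multiple) who need gold-standard benchmarks: families of
related networks whose true node correspondence is known by
construction, at arbitrary sizes and phylogenies.

## What it does

An ancestral network is grown from a small seed and repeatedly
*bifurcated* along a binary phylogeny `T`: at every internal node the
network `G = (V, E, F)` is duplicated (functional annotations `F`
inherited) and each copy grows independently to its child's target
size. Leaves form the family. Four growth models supply the "add one
node" rule:

| model  | rule | defaults |
|--------|------|----------|
| DMC    | duplicate anchor; delete one of each parallel edge pair w.p. `q_mod`; add the complementary edge w.p. `q_con` | `q_con = 0.5`, `q_mod = 0.4` |
| DMR    | duplicate anchor; delete each copied edge w.p. `q_del`; attach to any other node w.p. `q_new/N` | `q_new = 0.85`, `q_del = 0.4` |
| CG     | crystal growth: exactly `δ` edges, favouring the current targets' neighbourhoods | `δ = 4` |
| STICKY | assigned degree `d ~ c·d^{-γ}` on `{1..d_max}`; edge to node `j` w.p. `min(1, d·d_j/Σd)` (stickiness product); one inserted edge removed w.p. `f_del` | `f_del = 0.55`, `γ = 1.6`, `d_max = 50` |

Singleton nodes are discarded and redrawn, so output networks are
singleton-free. Each node inherits its anchor's functional-orthology
(FO) lineage and keeps a non-null annotation with probability
`P_fO = 0.9`; groups spanning networks are the ground-truth alignment.
Cross-network similarity scores are Gamma draws — `Γ(0.94, 169.49)` for
orthologous pairs, `Γ(0.86, 42.00)` for background pairs — with ±10%
per-node multiplicative jitter, and per-node potential-ortholog counts
`N(v) = |{u : s(v,u) > T_s}|` (threshold `T_s = 45`) follow a
heavy-tailed law by construction.

The **netstats** side provides the validation toolkit: power-law degree
exponent fits (`P_d(k) ~ k^{-γ}` by log–log regression), local
clustering coefficients `CC = 2e/(k(k-1))`, the full 2–5-node graphlet
catalogue (30 graphlets — the edge plus the 29 classic multi-node
graphlets — with 73 automorphism orbits), graphlet degree distribution
agreement (GDDA), and maximum-likelihood Gamma fits. A grid-search
**calibration** module refits growth-model parameters to any reference
feature summary.

## Worked example

```r
library(ppifam)

fam <- synthesizeFamily(presetTree("pairwise"), modelParams("dmc"), seed = 1)
fam
#> FamilyBundle: 2 networks, 50 FO groups, 336755 similarity records
#>   A              3000 nodes   26338 edges
#>   B              4000 nodes   37787 edges

networkSummary(fam@networks$B)
#>  name nodes edges edgesPerNode degreeExponent meanClustering
#>     B  4000 37787      9.44675       1.397131      0.2365772

pc <- potentialOrthologCounts(fam@similarities, threshold = 45)
sum(pc$count > 0)
#> [1] 6596

writeFamily(fam, "family1")
# family1/: A.net  B.net  A-B.sim  orthology.tsv  manifest.json
```

The two leaves have exactly their phylogeny-specified sizes (3,000 and
4,000 nodes, evolved from a 2,000-node ancestor). `edgesPerNode` of
9.4 sits in the realistic range for curated PPI networks; 6,596 of the
6,870 score-carrying nodes have at least one potential ortholog above
the bit-score threshold. `orthology.tsv` lists each FO group with its
`network:node` members — the ground truth an aligner is scored
against — and the run is byte-reproducible from `seed = 1`.

A command-line front end mirrors the R API:

```sh
exec/ppifam suite --name pairwise --out bench/ --seed 7 --families 10
exec/ppifam stats --net bench/pairwise/dmc/family_1/A.net
```

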