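---
title: "Network features, ensemble training and voting: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network features, ensemble training and voting: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models behind `adrnet`, the parameters that
matter, the numerical conventions the implementation pins down, and the
places where the design was genuinely open and a choice had to be made.

## The modeling premise

The package rests on guilt-by-association: proteins involved in the same
adverse drug reaction (ADR) occupy nearby regions of the interactome and
share function. Every quantity the classifiers consume is therefore a
*network* property of a protein relative to an ADR seed set — no sequence,
structure or chemistry enters. Two assumptions follow. First, the
interactome must be treated as a single connected substrate: diffusion and
panel distances are undefined across components, so `load_interactome()`
restricts to the largest connected component by default (retained/dropped
counts are logged). Second, the curated seed proteins must be a reasonable
sample of the ADR module; seeds missing from the network are dropped with a
warning rather than failing the run, since association tables routinely
contain accessions outside any given interactome build.

## The eight features

**Diffusion score.** The seed-propagation score is implemented as random
walk with restart: the fixed point of `s = α W s + (1 − α) e`, where `W` is
the column-normalized adjacency matrix and `e` spreads unit mass uniformly
over the seeds. This is a standard, well-defined member of the family of
network diffusion scorers; the restart weight `α` (default 0.5, exposed)
sets the diffusion range — small `α` keeps mass on the seeds, large `α`
approaches the stationary walk. The iteration is a contraction for `α < 1`,
stops when the largest absolute score change drops below `tol = 1e-6`
(cap `max_iter = 1000`, non-convergence is a warning, not an error), and on
isolated-node-free graphs the scores sum to exactly 1 — an invariant the
tests assert. Zero-degree nodes would leak mass (their adjacency column is
zero), which the default LCC restriction avoids.

**Topology.** Degree centrality is normalized by `n − 1` and betweenness by
`(n − 1)(n − 2)/2` with endpoints excluded and shortest-path multiplicity
split fractionally (Brandes semantics, as computed by igraph). Normalization
makes networks of different sizes comparable; the clustering coefficient of
a node with degree < 2 is defined as 0.

**Cluster dispersion.** Two non-overlapping partitions of the network are
built once per network: spectral clustering of the diffusion state distance
(DSD) matrix, and Louvain modularity. DSD characterizes node `u` by its
expected-visit profile over random-walk steps `0..t` and takes L1 distances
between profiles; the finite-walk form with `walk_length = 5` (exposed) is
used rather than the convergent infinite-walk form — five steps already
mix local neighborhood information on networks of the sizes handled here,
and the finite form is exactly testable by hand on toy graphs. Spectral
clustering uses the affinity `exp(−d/σ)` with `σ` = median off-diagonal
DSD, the symmetric normalized graph Laplacian embedding, and seeded k-means
(`nstart = 10`). The number of spectral modules defaults to `round(n/15)`;
published cluster counts for comparable pipelines are internally
inconsistent, so no specific count is targeted and the parameter is
exposed. Degenerate requests are honored: `k = 1` yields one module and
`k = n` yields singletons (k-means cannot split automorphic nodes whose
spectral embeddings coincide, so the singleton partition is returned
directly). The per-protein feature is
`100 · |modules occupied by seeds ∪ {v}| / |seeds ∪ {v}|`. The original
description of this feature gives only its direction (ADR proteins
concentrate in few modules); this formula is this package's
operationalization and reproduces that direction — planted-module members
score lower than matched background nodes, a property the tests check on
synthetic fixtures. A known limitation of the DSD partition here: the
published "K1" pipeline additionally merges dense bipartite subgraphs into
the clustering; that under-specified step is omitted and DSD + spectral
clustering alone carries the feature.

**Function conservation index.** GO terms enriched among the top-`k`
propagated proteins (default `k = 100`, exposed; the source description
says only "top ranking") are found by one-sided Fisher's exact test with
Benjamini–Hochberg correction at `α = 0.05`. BH is this package's choice —
the method description names Fisher's test but no correction, and testing
hundreds of GO terms uncorrected would be indefensible. The index of a
protein is `|GO(v) ∩ E| / |E|` over the enriched set `E`, i.e.
`1 − Hamming/|E|` against the all-ones indicator: 1 means the protein
carries every enriched function. The denominator is `|E|`, not the GO
universe — the "1 = full overlap" anchor forces that reading. When nothing
is enriched the index is 0 with a warning; prediction-time proteins lacking
annotations likewise get 0 rather than failing.

**Safety-panel distance.** The first quartile of BFS hop distances from the
protein to every reachable panel member (self-distance 0 counts). Quartiles
interpolate linearly between order statistics (R's default type 7), pinned
so results are bit-stable. A protein that reaches no panel member gets the
network's node count as an off-scale sentinel, preserving the "far = large"
ordering without introducing infinities.

## Training sets

DIAMOnD expansion grows the seed module one protein per step, adding the
candidate whose connectivity to the current module has the smallest
hypergeometric tail probability `P(X ≥ k_s)` (population = node count,
successes = module size, draws = candidate degree); ties break toward lower
degree, then lexicographic accession, making the ranking fully
deterministic. The DIAMOnD *score* is defined as `1 − p`, giving the 0–1
"higher is closer" scale the 0.6–0.9 thresholds presuppose. Positives are
the seeds plus all ranked proteins at or above the threshold; negatives are
drawn uniformly (seeded) from the rest of the network below the threshold
(unranked nodes count as score 0), at `round(ratio × positives)`. Whether
negatives should come from the whole network or a narrower candidate pool
is not specified upstream; whole-network sampling is used as the least
informative choice. Threshold and ratio menus ({0.6, 0.7, 0.8, 0.9} ×
{1, 1.5, 3, 5}) are validated but overridable; the package enumerates
whatever grid the configuration specifies.

## Classifiers, selection and voting

All three families see z-score-standardized features (standardization is
this package's addition — SVM and the network need comparable scales, and
the statistics are always taken from training folds only, never from
held-out rows). Grid points are scored by mean ROC AUC under stratified
5-fold cross-validation, the selection metric used throughout (the upstream
description reports mean AUC for its best models without naming its
criterion); the winner is refit on all rows. SVM uses an RBF kernel with
Platt-style probability calibration as provided by libsvm; RF uses 500
trees with `mtry` and a depth cap (`maxnodes = 2^depth`) on the grid. The
neural network is a small feed-forward net — ReLU hidden layers (1 or 2),
logistic output, stochastic gradient descent on cross-entropy with
mini-batches of 32 — implemented in the package because that exact
architecture is part of the training contract. Default grids (SVM
`C ∈ {0.1, 1, 10, 100}`, `γ ∈ {10⁻³..1}`; RF `mtry ∈ {2, 3, 8}`,
depth `∈ {3, 5, 10, ∞}`; NN learning rate `∈ {10⁻³, 10⁻², 10⁻¹}`, epochs
`∈ {50, 200}`, layers `∈ {1, 2}`, neurons `∈ {8, 16}`) are defaults, not
reproductions of any published winning parameters. Every source of
randomness — folds, sampling, initialization — is keyed to one integer
seed, and identical inputs reproduce CV reports byte for byte.

Posteriors are the probability of the *predicted* class, hence ≥ 0.5; this
is the `pᵢ` in the consensus score `c = Σᵢ pᵢ · classᵢ ∈ [−3, 3]`. Three
conventions were open and are pinned here: `c = 0` maps to the negative
class (no liability call without positive evidence); the red-flag rule
returns the unanimous class when there is no dissenter; and no minimum
posterior is demanded of the dissenter.

## The synthetic generator

`generate_fixture()` emulates the study conditions: a preferential
attachment interactome (heavy-tailed like real interactomes; the pinned
convention — `m` initially unconnected nodes, each newcomer attaching `m`
edges with probability ∝ degree + 1 — makes the edge count exactly
`m(n − m)` and therefore testable), a planted ADR module selected by seeded
BFS and densified with probability 0.3 per absent internal edge, module GO
terms carried by planted nodes at rate 0.8 against a 0.1 background, and a
48-member safety panel sampled with weight `0.5^d` in the hop distance to
the module — 48 matching the size of a standard preclinical safety screen
panel. Half the planted nodes (rounded up) become the ADR seed set; the
held-out half are the recoverable positives. Defaults (`n = 1000`, `m = 3`,
module 30) are the package's study conditions and are what the test suite
and `scripts/acceptance.R` exercise; unit tests run the same generator at
`n = 150–500` to stay fast. What the generator does **not** emulate: the
degree-correlation and study-bias structure of literature-curated
interactomes, multi-ADR overlap (one module per fixture), annotation depth
heterogeneity, and identifier noise. Passing tests on fixtures therefore
demonstrate correctness of the machinery and recoverability of a planted
signal — not real-data performance, which depends on proprietary composite
inputs this package does not ship.

On these fixtures the planted-module recovery is strong for each family
individually (the acceptance checks require mean random-forest CV AUC
≥ 0.80 over five seeds, and the feature-level directional claims hold at
rank-test p < 0.01). One documented shortfall: with a single synthetic ADR
the three classifiers train on identical rows and features, their errors
correlate strongly, and the random forest tends to dominate — so jury and
consensus voting track, but do not reliably beat, the best single
classifier here. The improvement reported for voting on real data comes
from averaging over many ADRs with much weaker, noisier individual models;
that regime is not reproduced by one planted module, and the corresponding
acceptance check documents the gap rather than relaxing it.

## Degenerate inputs and other conventions

Self-loops are dropped with a warning; duplicate undirected edges collapse;
accessions are opaque case-sensitive strings and no identifier mapping is
attempted. `top_ranked()` breaks score ties lexicographically. Ratio
metrics with zero denominators are reported as 0 and flagged rather than
NaN. ROC AUC is computed by the Mann–Whitney rank formula (midranks for
ties); AUPRC is average precision. GAF input keeps columns 2 and 5 and
drops `NOT`-qualified rows; GO identifiers must match `GO:` + 7 digits.

## Known limitations

Beyond the fixture caveats above: annotations are used as given (no GO
ancestor propagation); the PT→SOC mapping is whatever the association table
says (no MedDRA service); SOC-level models simply union member-ADR protein
sets; and no attempt is made to reproduce published cluster counts or
real-data performance figures, which depend on a specific proprietary
network build and curated association snapshots.
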