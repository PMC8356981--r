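---
title: "Methods: repeatable community detection and hub identification in weighted brain networks"
author: "netRepeat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: repeatable community detection and hub identification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A structural brain network (SBN) is a weighted undirected graph whose nodes
are atlas-defined brain regions and whose edges summarise white-matter
connectivity. Its mesoscale organisation — the partition of nodes into
communities, and the cartographic roles (connector or provincial hub) derived
from that partition — depends on two upstream choices: how the graph is
constructed from the per-edge metrics, and which community-detection
algorithm is applied. If a (construction scheme, algorithm) pair does not
reproduce the same communities when the same brain is scanned twice, nothing
downstream of that partition can be trusted. `netRepeat` implements a
complete test–retest evaluation pipeline for such pairs, together with a
synthetic cohort generator that makes every stage testable against planted
ground truth.

## Pipeline overview

For each scheme–algorithm pair the pipeline computes, over a cohort of
subjects scanned twice:

1. per-subject, per-session connectomes under the scheme;
2. hard partitions per connectome, with their quality index `Q`;
3. a quality permutation test of `Q` against degree- and strength-preserving
   surrogates;
4. group-averaged between-scan agreement of partitions (normalised mutual
   information, NMI) with a label-permutation bootstrap p-value;
5. a consensus matrix over all subjects × sessions, topologically filtered
   and re-partitioned into a representative partition, scored by its mean NMI
   against the individual partitions;
6. nodal participation coefficients `P_i` and within-module z-scores `z_i`,
   their two-session ICC, hub classification, and a per-node agreement index;
7. two-way ANOVAs over the scheme × algorithm grid and a final gated ranking
   (between-scan NMI > 0.9, bootstrap p < .05, quality p < .05, then ordered
   by consensus similarity).

## Graph construction

**Edge-weight conventions.** Weights encode connection strength; all outputs
are normalised to a maximum edge weight of 1 with a zero diagonal. The
weight-to-distance transform used for shortest paths and spanning trees is
`d = 1/w`; a zero weight means "no edge", never distance zero.

**OMST filtering.** Orthogonal minimal spanning trees are extracted
iteratively (Kruskal on `1/w`, deterministic lexicographic tie-breaks), each
tree's edges removed before the next round. After each accumulation the
global cost-efficiency `J = E_glob − cost` is evaluated, where `cost` is the
fraction of the input's total edge weight captured — a dimensionless choice
that makes `J` scale-invariant. The accumulation maximising `J` is returned
together with the whole `J` curve (`maxTrees` defaults to 10) so the
selection can be audited. On graphs whose weights carry no heavy tail — the
synthetic cohorts below are uniform on `[0.5, 1]` — the optimum typically
retains a single spanning tree; this is the honest outcome of the objective,
not a failure of the filter, and it has consequences for the thresholded
schemes discussed below.

**Metric integration.** The multi-metric schemes combine min–max-rescaled
metrics (MD and RD inverted so that "high = stronger connection" semantics
align) as a linear combination whose coefficients are proportional to each
metric's mean pairwise dissimilarity from the other selected metrics,
`1 − |Pearson r|` over the shared nonzero edges, normalised to sum to one.
This up-weights metrics carrying complementary information and down-weights
redundant ones. The exact functional form is this package's own declared
choice; alternatives (e.g. distance correlation) would slot into the same
interface.

**The seven schemes.** Three OMST schemes (NS alone; NS+FA integrated; all
nine metrics integrated) and four sparsity-matched thresholding schemes
(threshold on NS or FA, optionally re-weighting the surviving edges with FA,
MD or NS). The thresholded schemes keep the top-K edges with deterministic
lexicographic tie-breaks.

**The sparsity anchor.** `applyScheme(..., referenceSparsity = "auto")`
matches the thresholded schemes to the nine-metric OMST scheme's sparsity
exactly. Because the synthetic cohorts drive the OMST optimum to a single
spanning tree, "auto" equals tree density there, and a thresholded graph at
exactly tree density is connected only if it happens to be a spanning tree —
probability essentially zero. The grid configuration therefore carries its
own anchor, `referenceSparsity = 0.15` by default (about three trees' density
on 40 nodes, comparable to published OMST sparsities on 90-node structural
networks), with "auto" still available. Disconnected scheme outputs are not
repaired: the affected subject-sessions are dropped with a logged diagnostic,
and a pair aborts (without stopping the grid) when fewer than two subjects
remain.

## Community detection

Five hard criteria are optimised by one two-phase greedy (Louvain-style)
engine: weighted Newman modularity; the Reichardt–Bornholdt configuration
null at resolution γ; the Ronhovde–Nussinov Potts objective with non-edge
penalty γ; the Arenas–Fernandez–Gomez self-loop criterion (uniform self-loops
of weight r); and linearised Markov stability at time t. Defaults are
`rb γ = 1`, `afg r = 0`, `stability t = 1` — each reducing exactly to Newman
modularity — and `rn γ = 0.25`. The rn default deserves a note: for
max-1-normalised weighted graphs the Potts penalty must sit below the typical
within-module weight per missing pair (otherwise weakly attached nodes peel
off into singletons) and above the between-module weight density (otherwise
modules merge); γ = 0.25 sits centrally in that stability window, and at
γ = 0.5 the objective demonstrably prefers singleton-peeling solutions on the
benchmark cohorts. Scales remain user-settable everywhere, and further
criteria can be added through `registerCommunityAlgorithm()`.

Optimizer determinism: sweep order is shuffled from the seed; gain ties break
toward the lowest community id; nodes whose best gain is negative are
isolated. Five seeded restarts are run and the all-in-one and singleton
partitions are always evaluated as baselines, so the returned partition is
never worse than either. On every connected fixture graph with ≤ 8 nodes the
engine attains the exhaustively enumerated global Newman optimum (tested).

The soft method is a link-community cover: edges are clustered by single
linkage on the Jaccard similarity of their endpoint neighbourhoods, the
dendrogram is cut at maximal partition density (ties toward fewer clusters),
and edge communities are projected onto nodes, which may then hold several
memberships.

## Similarity, nulls, consensus

**NMI.** Hard-partition NMI uses the `2I/(H1+H2)` normalisation — the most
common convention in this literature; when both partitions are
single-community (both entropies zero) the value is defined as 1 rather than
NaN, and a single-community partition against a multi-community one scores 0.
Cover NMI follows the Lancichinetti–Fortunato–Kertesz construction with the
standard unmatchable-community constraint. The two normalisations differ
slightly; on near-identical pairs they agree within 0.05 (tested), which is
why hard and soft agreement values can be compared only qualitatively.

**Bootstrap.** The between-scan significance test permutes the node-to-label
assignment of the second partition, preserving its community-size profile
while destroying node correspondence, with the add-one p-value
`(1 + #{null ≥ obs})/(B + 1)`. Whether the original procedure resampled
subjects or node labels is not recoverable from the source description; the
node-label permutation null is this package's documented reading, and the
group-level variant permutes within every subject before averaging.

**Surrogates.** Degree sequences are preserved exactly by double-edge swaps
with per-swap connectivity checks; the original weight multiset is then
re-assigned by rank-matching (heavier weights onto edges joining stronger
nodes) and iterative proportional adjustment until every node strength is
within 1% (typically 0.1%) of the original; the achieved error is recorded on
the output. Quality p-values use the same add-one convention, so p is never
zero; 1000 surrogates is the reference setting, 99 the fast screening setting
used in the test suite.

**Consensus.** Co-clustering counts over all subjects × sessions are divided
by the number of partitions; the diagonal is reported as 1 but zeroed before
filtering (self-loops are meaningless to spanning trees). Instead of an
arbitrary threshold-and-iterate loop, the probability matrix is OMST-filtered
once and re-partitioned with the same algorithm that produced the individual
partitions. Two degenerate cases are defined explicitly. A binary probability
matrix (every pair co-clusters always or never) is perfect agreement: its
connected components *are* the representative partition, and running a
detection algorithm could only subdivide them spuriously. A disconnected
non-binary probability graph is partitioned per component with label
offsets. These definitions make consensus idempotent: the consensus of
copies of one partition returns that partition exactly (tested).

## Hub cartography and reliability

`P_i = 1 − Σ_s (κ_is/k_i)²` and `z_i` are computed on node strengths
(weighted degrees), consistent with weighted SBNs; `z_i` standardises
within-module strength by the module's mean and *population* (1/n) standard
deviation, the original cartographic convention; zero-spread modules assign
`z = 0`, isolated nodes `P = 0`. Hubs are nodes with `z ≥ zHub` (boundary
counts as hub); connectors additionally have `P > pConnector`. The defaults
`zHub = 2.5`, `pConnector = 0.30` are the classical cartographic thresholds
and are exposed as configuration: note that within small modules (10 nodes in
the default cohorts) a z-score of 2.5 is close to the attainable maximum, so
at these thresholds few or no hubs are detected and the agreement indices sit
at 0 — threshold sensitivity is intrinsic to this cartography, which is why
the planted-hub check injects an unambiguous connector instead of relying on
threshold crossings.

The agreement index of a node is the fraction of subjects in which its role
is detected in *both* sessions (per-subject logical AND, then the average);
value 1 marks hubs detected consistently across the whole cohort and both
scans. Test–retest reliability of nodal `P` and `z` uses ICC(2,1) — two-way
random effects, absolute agreement, single measurement — the standard choice
for test–retest designs; the variant is isolated in one function and constant
tables are defined as ICC 0. The scheme × algorithm grid is assessed with a
fixed-effects two-way ANOVA (per-subject values as replicates), p-values
reported raw and Bonferroni-adjusted across the three effects.

## The synthetic cohort generator

The generator emulates exactly the statistical structure the analysis
assumes, nothing more: symmetric, non-negative, zero-diagonal, connected
weighted graphs with planted modular ground truth; nine correlated edge
metrics sharing one zero pattern; and a second session derived from the first
by controllable noise.

* **Graphs**: planted-partition sampling with within/between edge
  probabilities `pIn`/`pOut` and uniform weights. Disconnected realisations
  are repaired by adding minimal-weight bridges between the smallest-indexed
  nodes of components, so planted densities are minimally disturbed.
* **Metric stacks**: `NS` is the base matrix; each other metric is a
  standardised mixture `ρ·base + √(1−ρ²)·noise` mapped to a positive range,
  so its edgewise correlation with the base is ≈ ρ in magnitude; MD and RD
  are generated on an inverted scale (high where NS is low) to mimic
  diffusivity semantics; ED is the Euclidean distance between random 3-D
  node coordinates (shared across a subject's two sessions), masked to the
  base topology.
* **Session 2**: degree-preserving double-edge swaps rewiring a chosen
  fraction of edges (edge count and degree sequence preserved), then
  multiplicative log-normal weight noise (applied on the log scale, keeping
  weights positive without clipping).

**Study conditions.** The defaults — 20 subjects × 2 sessions, 40 nodes in 4
modules of 10, `pIn = 0.8`, `pOut = 0.05`, weights uniform on `[0.5, 1]`,
session noise `weightNoiseSd = 0.1` and `rewireFraction = 0.05`, metric
similarity profile FA 0.7, MD 0.6, RD 0.6, PS 0.9, SLD 0.8, TV 0.7, TL 0.5 —
were chosen once as a desk-scale cohort with clearly recoverable structure
and realistic inter-metric correlations, and are not tuned thereafter. There
is no authoritative generative model for between-scan variability in real
test–retest data; this noise model is a declared stand-in, not an inference.

**What passing tests do and do not show.** The generator produces uniform
(not heavy-tailed) weights, weights independent of module membership, no
spatial embedding beyond ED, no hemispheric or anatomical organisation, and
module sizes far smaller than the 90-region atlas graphs of real studies.
Passing the suite demonstrates that every stage implements its contract and
that the pipeline's rankings respond to controlled noise in the right
direction; it does not certify behaviour on real connectomes, where weight
distributions, density and module structure differ substantially.

## Problem sizes in the shipped tests

The test suite and acceptance script use 40-node cohorts of 4–20 subjects,
100-seed recovery sweeps, 99–199 surrogates/resamples for permutation and
bootstrap tests, and a 7 × 4 grid over 12 subjects — sizes chosen so the full
analysis remains a desk-scale computation while keeping every statistical
check adequately powered. The reference surrogate count (1000) is available
behind the same arguments.

## Known limitations

* The full published battery of 33 community-detection algorithms is not
  reproduced; the four winning multi-scale criteria, a Newman baseline and
  one representative soft method exercise every code path, and the plug-in
  registry accepts more.
* Sparsity-matched thresholding can disconnect graphs; the pipeline drops
  such subject-sessions rather than repairing them.
* Hub detection at the classical thresholds is scale-sensitive (see above);
  results should be read jointly with the threshold configuration.
* Manifest cohorts carry one matrix per session, so only the NS-based
  schemes (A and D, the latter with an explicit sparsity) are available for
  them; full grids require metric stacks, which the generator provides.
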