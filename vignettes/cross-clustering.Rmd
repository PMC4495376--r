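---
title: "Methods: layered cross-clustering for confounder detection in breath profiles"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: layered cross-clustering for confounder detection}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breathclust)
```

## The problem

A breathomics study measures the intensities of volatile organic
compounds (VOCs) in exhaled air across a cohort, yielding a peak matrix
**X** with one row per sample and one column per metabolite. The
clinical question is usually a sample grouping — disease vs. control,
disease subtypes — but exhaled air also carries strong signatures of
smoking, nutrition and the ambient environment. When such a confounder
moves many metabolites coherently, an unsupervised clustering of the
samples follows the confounder, not the disease, and the disease signal
is invisible in the full matrix.

The remedy implemented here is *cross-clustering*: first cluster the
**metabolites** by co-expression, then re-cluster the **samples**
separately inside each metabolite cluster. Metabolite clusters that
encode a confounder then reveal themselves by explaining the confounder
annotation (high external F-measure) while failing on the disease
annotation, and can be set aside. Everything is unsupervised; the
annotations enter only at the evaluation stage.

## Pairwise relations

Three measures are supported, chosen per axis:

* **Pearson correlation** of two observation vectors (linear
  co-expression),
* **Spearman correlation** (Pearson on average ranks; monotone
  co-expression),
* **Euclidean distance** (profile proximity).

Correlations are similarities in [−1, 1]; by default their **absolute
value** is taken, because for co-expression screening a strong negative
correlation is as informative as a positive one. Euclidean distances
are dissimilarities.

Both representations are needed downstream (hierarchical clustering and
the silhouette consume dissimilarities, transitivity clustering
similarities), so matrices are interconverted by the magnitude
complement: every entry becomes `M − |value|` with `M` the maximum
absolute entry of the whole input matrix. The diagonal is included in
`M` deliberately: for a correlation matrix the diagonal is 1, anchoring
the conversion at the familiar `d = 1 − |r|`, and no off-diagonal entry
can exceed it. After converting a similarity the diagonal is forced to
zero (warning if it was not already), since `d(x, x) = 0` is required by
the clustering and silhouette code; for correlation inputs the formula
already gives zero and the forcing is a no-op.

Degenerate inputs are tolerated rather than fatal: an all-constant
metabolite (common in sparse peak tables) has no defined correlation,
so its off-diagonal similarities are set to 0 with a warning naming the
object — it simply clusters with nothing. Missing intensities are
rejected by default; an opt-in pairwise-complete mode computes each pair
over co-observed positions, requiring at least 3, which is the smallest
overlap for which a correlation is better than noise-free guesswork.
There is no principled default for missing-data handling in peak
matrices, so the package makes rejection explicit instead of imputing
silently.

## Hierarchical agglomerative clustering

Standard bottom-up agglomeration over a dissimilarity matrix with
single, complete or average linkage — the three monotone linkages, kept
deliberately to this set so that merge heights are guaranteed
non-decreasing and the merge tree is well-formed for every input.
(Centroid-family linkages can invert heights and were left out.)

Two determinism choices matter on real data, which contains ties:

* **Tie-breaking.** When several cluster pairs share the minimal
  distance, the pair that is lexicographically smallest by (smallest
  member id, then the other cluster's smallest member id) is merged,
  with ids compared under C collation. Results are therefore identical
  across platforms and input orderings.
* **Cut semantics.** Cuts are specified by the cluster count k (undo
  the last k − 1 merges), not by a height, because the sweep consumed by
  the quality curves is naturally indexed 1..N and height cuts are
  ambiguous exactly at tied heights.

The implementation updates distances by Lance–Williams recurrences; the
test suite checks its merge heights against a naive oracle that
re-derives every cross-pair linkage distance from the original matrix
at every step (instances up to 8 objects, all three linkages, tolerance
1e−9), and against `stats::hclust` on tie-free random instances.

## Transitivity clustering as weighted cluster editing

A similarity matrix and a threshold T define a cost graph with
`cost(u, v) = s(u, v) − T`; pairs with strictly positive cost are edges.
The clustering is the disjoint-clique graph reachable from the
thresholded graph at minimal edit cost, where deleting an edge costs
`cost(u, v)` and inserting a missing one costs `−cost(u, v)`. Zero-cost
pairs are free and treated as absent edges — the boundary `s = T`
therefore does not create an edge, which makes the sweep behaviour at
exact threshold hits predictable. This `s − T` formulation is the
standard weighted cluster-editing cost model; the threshold has the
interpretation that, at an optimal solution, the average similarity
within every non-singleton cluster is provably above T (asserted on all
exactly solved instances in the tests).

The optimisation is NP-hard, so the solver is layered:

* **Connected-component decomposition** over positive-cost pairs first;
  no positive pair crosses components, so this is loss-free.
* **Exact branch-and-bound** for components of at most `exact_cap = 13`
  vertices: vertices are assigned to clusters in canonical order, and a
  branch is pruned when the incurred cost plus an admissible bound (for
  every unplaced vertex, the cheapest attachment of that vertex to the
  clusters formed so far) reaches the best known cost. The search is
  warm-started by the heuristic. The cap keeps the worst case bounded
  while covering typical component sizes at sensible thresholds;
  exactness is verified against full partition enumeration on 6-vertex
  instances (Bell(6) = 203 partitions) in the acceptance tests.
* **Seeded pivot heuristic** for larger components: pick a pivot, absorb
  its positive-cost neighbours, repeat; then greedily relocate single
  vertices to a local cost minimum; best of `restarts = 25` seeded
  restarts. Simple, deterministic under the seed and empirically within
  5% of the exact optimum on ≥ 95% of random test instances. A
  layout-based heuristic would add complexity without benefit at the
  matrix sizes this package targets (tens to low hundreds of objects).

## Cluster validity

**Silhouette.** For object i, `a_i` is the mean dissimilarity to its
co-members and `b_i` the smallest mean dissimilarity to any other
cluster; `S(i) = (b_i − a_i)/max{a_i, b_i}` and the overall value is the
mean over objects. Singletons score 0 (Rousseeuw's convention — the
formula leaves `a_i` undefined for them, and 0 is the neutral choice
that neither rewards nor punishes outlier isolation). A single-cluster
partition has no between term at all: the value is undefined (`NA` with
a warning) and sweep curves *omit* the point rather than coercing it to
0, since a coerced 0 could silently win or lose the argmax.

**F-measure.** Against a gold standard K built from one annotation
label (each distinct value = one class):
`F = (1/Σ|K_i|) Σ_i |K_i| max_j 2 t_ij / (|C_j| + |K_i|)` with `t_ij`
the contingency counts. The max is taken over all clusters j — the
printed range of the inner index in some statements of this formula is
a typographical artefact; the standard class-wise best-match reading is
used. F lies in [0, 1] and equals 1 exactly for identical partitions
(verified exhaustively over all pairs of partitions of 5 objects).

**Model selection.** `best_parameter()` takes the sweep argmax; ties
break toward the *smaller* parameter — fewer clusters or a lower
threshold — i.e. toward the more parsimonious model.

## Multidimensional scaling

The embedding minimises raw stress
`S(z) = Σ_{i≠j} (d_ij − ‖z_i − z_j‖)²`. The optimiser is SMACOF
majorization (Guttman transform), initialised by classical scaling.
This pairing is deterministic — the seed is consulted only if classical
scaling yields fewer positive eigenvalue directions than requested and
the remaining coordinates must be jittered — and majorization
guarantees a non-increasing stress sequence, which the tests assert per
iteration. Defaults: `max_iter = 300`, relative improvement tolerance
`tol = 1e−6`; both are generous for matrices of this scale. Zero
distances between distinct objects (duplicated profiles) are accepted;
the corresponding majorization weights are simply dropped for those
pairs at iterations where the embedded distance is zero. Coordinates
are identified only up to rotation, reflection and translation, so all
tests compare embedded distance matrices, never raw coordinates. PCA is
deliberately not offered here: the quantity the clustering consumed is
the pairwise relation, and the embedding should preserve exactly that.

## The workflow and its defaults

`cross_cluster()` runs: metabolite relation → metabolite clustering →
cut selection → subset split → per-subset sample relation, sample
sweep, F-measure curves per label → ranking. Defaults:

| stage | default | rationale |
|---|---|---|
| metabolite relation | absolute Pearson, converted to `1 − abs(r)` | co-expression screening |
| metabolite clustering | HAC, average linkage | robust middle ground between chaining (single) and outlier sensitivity (complete) |
| cut selection | silhouette-optimal k | internal, annotation-free model selection; a fixed k or threshold is configurable when prior knowledge exists |
| subset filter | `min_subset_size = 3` | clusters of 1–2 compounds cannot support a meaningful sample dissimilarity |
| sample relation | Euclidean distance, computed separately per subset | sample proximity within one metabolite signature |
| sample clustering | HAC sweep over k = 1..N | the F-measure curves need the full family of cuts |

The full-matrix baseline is always computed, because every conclusion
the screen supports — "this subset explains the label better/worse than
all metabolites together" — is a comparison against it. Both clustering
stages accept transitivity clustering instead of HAC via the config.
All randomness (the transitivity heuristic) is derived from the single
config seed, so a run is reproducible end-to-end; two runs with the
same config produce byte-identical ranking tables.

## The synthetic generator

`generate_artificial()` emulates an idealized planted-structure study:
16 samples carrying three independent categorical labels ("health"
5/5/6, "smoking" 9/7, "nutrition" 4/4/4/4; each label assigned by an
independent random permutation honouring the exact counts) and three
groups of 4 metabolites, each tied to exactly one label. Every
intensity is drawn from a normal distribution whose mean depends only
on the metabolite's group and the sample's value of the group's label.

Default geometry (module-owned, stated here because it defines what the
bundled tests demonstrate):

* noise SD 1, baseline mean 10;
* consecutive label-value means 6 SDs apart (`level_step = 6`) — i.e.
  clearly separated groups, as appropriate for a proof-of-concept
  dataset;
* the smoking group's two means are separated by `confounder_dominance
  = 2` times the **total spread** of the health group's means (24
  intensity units against 12). This makes smoking the dominant axis of
  variation of the full matrix, so the baseline sample clustering locks
  onto the smoking split — the phenomenon the workflow exists to
  detect. The factor 2 is the smallest round factor that makes the
  dominance robust across seeds against the nutrition group's spread
  (18 units across its four levels).

What the generator does *not* emulate: instrument noise structure
(heteroscedasticity, detection limits, censoring), correlated noise
within metabolite groups beyond the shared mean shifts, missing peaks,
batch effects, or confounders correlated with the disease label (labels
here are independent by construction). Passing tests on this fixture
therefore demonstrate the machinery — planted-group recovery,
silhouette model selection, confounder dominance and its resolution —
not performance on real breath data, where separations are far smaller
and confounders are correlated with outcomes.

## Problem sizes and determinism in the test suite

The bundled tests run at desk scale, chosen so the full suite completes
in well under a minute of compute per module: the 16 × 12 fixture for
end-to-end properties (20 seeds for the replication claims), 6-vertex
cost graphs (200 instances) for solver exactness against exhaustive
partition enumeration, instances of up to 8–10 objects for the HAC and
silhouette oracles, and 6–10 points for the MDS checks. All
stochastic tests fix their seeds explicitly.

## Known limitations

* The exact editing solver is exponential beyond ~13-vertex components;
  very dense similarity matrices at low thresholds fall back to the
  heuristic for the dominant component.
* HAC cut selection by silhouette evaluates k = 2..N only; a
  single-cluster "no structure" outcome is never selected. Inspect the
  curve when structure is doubtful.
* The F-measure, being class-weighted best-match, is insensitive to
  how the non-matched clusters partition the remainder; it is the
  screening statistic used here, not a general-purpose partition
  distance.
* Excel import/export and raw spectrum pre-processing (baseline
  correction, peak detection) are out of scope; inputs are
  pre-processed peak tables as delimited text.
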