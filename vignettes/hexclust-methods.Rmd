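---
title: "Adjacency-constrained clustering of binned cytometry maps: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adjacency-constrained clustering of binned cytometry maps: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hexclust)
```

## The problem

Mass cytometry (CyTOF) measures 30--40 protein markers on hundreds of
thousands of single cells per study. Fully manual gating does not scale to
that dimensionality, while clustering on a 2-D embedding alone discards most
of the marker information. `hexclust` implements a semi-automated middle
ground: cells are embedded in 2-D with t-SNE, the map is partitioned into
equal hexagonal bins, and the bins — not the cells — are clustered by
complete linkage in the *original* marker space, under the constraint that
clusters may only grow across bins that touch on the map. The result is a
set of clusters that are simultaneously coherent in marker space and
contiguous on the t-SNE map, at a granularity (thousands of bins rather than
hundreds of thousands of cells) where complete-linkage clustering is cheap
and reproducible.

Downstream, the package provides the cohort-level statistics this kind of
study needs: per-sample cluster occupancy, stratified rank-sum tests with
Benjamini–Hochberg correction, PCA plus type-II MANOVA variance
partitioning over clinical covariates, and a permutation screen for
associations between stimulated functional-marker frequencies and a
height-for-age z-score (HAZ), the standard anthropometric measure of
stunting.

## The clustering model

### Binning

The embedding is tiled with flat-top hexagons on an axial lattice. The
radius is chosen so the number of lattice positions covering the bounding
box (padded by one radius, so boundary points fall strictly inside a
hexagon) is as close as possible to `target_bins` (default 10,000).
Assignment converts each point to fractional axial coordinates and applies
cube rounding, which is exactly the nearest-center (hexagonal Voronoi) rule;
boundary ties are resolved deterministically by the rounding. Empty bins are
dropped. Each surviving bin carries the unweighted mean marker vector of its
member cells ("bin expression") and its cell count.

### Distances and adjacency

Distances between bins p and q are weighted Euclidean in marker space,

$$d(p,q) = \sqrt{\sum_i w_i\,(p_i - q_i)^2},$$

with one manually assigned, nonnegative weight per marker. Weights let the
analyst emphasise lineage markers and silence channels that should not drive
cluster boundaries; a zero weight makes a marker exactly inert. Two
non-empty bins are adjacent when their hexagons share a border. A non-empty
bin with no non-empty border neighbour receives exactly one fallback edge to
its nearest non-empty bin by center distance (tie: lowest bin id). One edge
is the minimal repair that removes isolation without inventing
neighbourhood structure; fallback edges count the same as border edges for
the clustering constraint. After the fallback no bin has degree zero.

### Two-phase constrained complete linkage

Agglomeration proceeds greedily. In the constrained phase, the pair of
clusters with the smallest complete-linkage distance *among pairs joined by
at least one cross-cluster adjacency edge* is merged; a merged cluster's
neighbour set is the union of its parents'. Because merging only ever
shrinks the adjacency graph, the constrained phase ends exactly when every
connected component of the bin graph has collapsed into one cluster. From
that point no adjacent pair exists and the remaining merges are ordinary,
unconstrained complete linkage. The phase therefore switches at most once,
and every cluster formed during the constrained phase induces a connected
subgraph of the bin adjacency graph.

Ties on merge distance are broken toward the lexicographically smallest pair
of cluster identifiers, where a cluster's identifier is its smallest member
bin id. The method itself does not need a tie rule (ties have measure zero
for continuous expression data), but a deterministic rule makes runs exactly
reproducible and lets the implementation be checked merge-for-merge against
a brute-force reference, which the test suite does on randomized instances.

The implementation caches, for each active cluster, its best partner among
higher-indexed clusters; complete-linkage distances only grow under merging,
so a cached partner needs re-scanning only when it took part in the last
merge. This is the standard nearest-neighbour-array scheme and keeps the
core loop (written in C++) near O(n²) for the few thousand occupied bins a
real map produces.

### Cutting and the minimum cluster size

Constrained merges are not height-monotone: a forced local merge can be
cheaper than an earlier global one. A height threshold is therefore
ill-defined, and the tree is cut *by merge order*: cutting at k undoes the
last k−1 merges. For an unconstrained (monotone) history this coincides with
the usual height cut.

A minimum cluster size in cells (default 1,500, matching the scale at which
a cluster is worth interpreting in a ~375,000-cell pooled analysis) is
enforced after cutting: while any cluster is too small, the smallest
offender is absorbed into the cluster it would join next in the merge
history — the earliest recorded merge that unites one of its bins with an
outside bin identifies the partner, and the offender joins the current
cluster containing that partner. This walks the dendrogram upward instead of
re-cutting at smaller k, so well-sized clusters are never disturbed. The
loop terminates because every absorption strictly reduces the cluster
count. Finally, cells inherit their bin's label.

## Statistical methods

**Occupancy.** The occupancy of cluster c in sample s is the fraction of
s's cells assigned to c; rows sum to one. Reference-pool cells (spiked-in
adult controls that help seed rare, age-depleted populations) are excluded
from sample rows but their clusters keep columns.

**Group tests.** Within each timepoint stratum, each cluster's occupancies
are compared between the two cohorts with a two-sided Mann–Whitney test —
exact when group sizes permit and there are no ties, otherwise the normal
approximation with mid-ranks and continuity correction — and BH-adjusted
across clusters *within the stratum*, because each timepoint is reported as
its own family. Flags are emitted at FDR 0.1/0.05/0.01/0.001.

**Variance partitioning.** PCA is applied to the occupancy matrix
(centered, unscaled); because rows sum to one the last dimension is
redundant, so all but the final non-degenerate component are retained. The
scores are modelled as a multivariate linear function of the clinical
covariates (batch set, week, location, ethnicity, sex, CMV status — all
categorical; week is binned sampling, not continuous age) and a type-II
MANOVA with the Pillai statistic is computed via `car::Anova`. The partial
variance share reported for a covariate is its Pillai trace divided by
s = min(df of the term, number of responses), the trace's attainable
maximum, so it always lies in [0, 1]. With a single response this reduces
exactly to the one-way ANOVA F and R²; the test suite asserts both this
reduction and null calibration of the Pillai p. Perfectly aliased covariates
raise an error naming the terms rather than silently dropping one — in a
small cohort, ethnicity can be a perfect proxy for location, and that is a
modelling decision the analyst must make, not the software.

**The HAZ screen.** Samples are first filtered by a k-means (k = 2)
consistency check: samples whose feature profile clusters with the wrong
stimulation condition are removed, since a donor responding to an acute
infection can look "stimulated" without the stimulus. Samples are then split
into group 0 (American; HAZ imputed as 0, the well-nourished reference),
group 1 (Bangladeshi, HAZ > −1.5) and group 2 (Bangladeshi, HAZ ≤ −1.5; the
boundary value is "more stunted"). For feature i and threshold θ the
*event* is

$$\frac{\mu_{i0}-\mu_{i1}}{s_{i,0}} \ge \theta
  \quad\text{and}\quad
  \frac{\mu_{i2}-\mu_{i1}}{s_{i,2}} \ge \theta,$$

where $s_{i,j}$ is the df-weighted pooled SD of group j with group 1. The
event is deliberately two-sided in design: a marker associated with stunting
should separate the less-stunted Bangladeshi group from *both* the
more-stunted group and the American reference. It is translation-invariant
and scale-equivariant, so units cancel.

The null is built by permuting HAZ among the Bangladeshi samples only —
the American pseudo-HAZ is an imputed constant, and shuffling a constant
into real scores would mix the reference into the contrast being tested.
Group sizes are preserved because the permuted values are the same multiset.
Per feature and θ, the permutation p is the add-one estimate
(1 + B)/(1 + N) of the event probability under the null; the FDR estimate at
θ is the plug-in ratio of mean null event count to observed event count,
capped at one. Candidates must show the observed event with p ≤ 0.05 and
FDR ≤ 0.2 at some θ in the sweep (default 0 to 2 in steps of 0.1); both the
per-θ table and the best-θ candidate list are returned, since a fixed-θ and
a best-over-grid reading are both defensible.

One calibration subtlety is worth stating. Because group 0 is never
permuted, the raw event probability p is *not* marginally uniform across
null features: a feature whose American mean happens to sit low has a small
p and simultaneously a false observed event. The quantity that is
super-uniform — and what both candidate calling and the tests rely on — is
the joint rate of (observed event AND p ≤ α), i.e. the event indicator
treated as the permutation test statistic.

**Validation and combination.** For a marker measured across several
populations, the first principal component of those correlated columns
(oriented so higher marker frequency gives higher score) is regressed on
the stunting indicator with a one-sided t-test in the direction "more
stunted → higher". With a single column this is exactly the one-sided
two-sample t-test. Training and validation p-values are combined with
Fisher's method (−2Σlog p ~ χ² with 4 df) — chosen because the two
cohorts are independent and the one-sided direction is fixed in advance.

## The synthetic-data generator

`simulate_cohort()` draws per-sample cells from a shared Gaussian mixture on
the asinh scale with diagonal covariance: 23 phenotype markers (plus 9
functional markers under stimulation, 32 in all), eight populations with
lineage means ≥ 4 spread-units apart, multinomial population counts with
cohort/week log-fold abundance effects and mild per-donor frequency noise,
and additive functional-marker shifts under PMA-ionomycin-like stimulation.
Bangladeshi donors receive a HAZ drawn from N(−1.5, 1) truncated to
[−4, 1], centred at the stunting threshold so both screen groups are
populated. `plant_haz_effect()` elevates chosen population × marker values
in the stimulated samples of more-stunted and American donors — the
U-shaped pattern the event criterion targets. `simulate_feature_cohort()`
generates the screen's input directly at the feature level (5/8/8 samples,
unit-variance features) and plants a 2-SD elevation across four correlated
population-features by default, because a real cytokine association
surfaces in several cell populations at once, and a single elevated feature
gives the plug-in FDR (null events over observed events) no denominator
headroom.

What the generator does *not* emulate: spillover and isotopic interference,
doublets, zero-inflation and heavy tails of real CyTOF intensities, batch
drift within a set, or any spatial structure in the t-SNE map beyond what
the mixture itself induces. Passing tests therefore demonstrate that the
algorithms recover planted structure under clean mixture conditions — they
do not certify performance on raw instrument data, where staining quality
and gating upstream of this package dominate.

## Numerical and scale choices

* asinh cofactor 5 (CyTOF community standard); configurable.
* QC drops samples with fewer than 3,000 cells, strictly less-than.
* Default downsampling of 6,000 cells per sample plus 30,000 reference
  cells mirrors the pooled-analysis design the package targets.
* t-SNE runs single-threaded Barnes–Hut (perplexity 60, theta 0.5, 2,000
  iterations by default) so a seed fully determines the embedding; the
  embedding is pluggable, and any (cells × 2) coordinate file can be
  substituted.
* The test suite and the acceptance script run the full pipeline at desk
  scale — 20 samples × 500 cells, ~2,000 tiling positions, minimum cluster
  size scaled to the same 0.4 % of pooled cells that 1,500 is of 375,000 —
  which a laptop CPU completes in about a minute while exercising every
  stage at full fidelity. Oracle checks run on randomized instances of up to
  200 bins, where brute-force re-scanning is exact and fast.
* Permutation counts: 5,000 for reported screens (the add-one p floor is
  then 1/5001), 1,000 in repeated power simulations.

## Known limitations

* t-SNE embeddings are seed- and implementation-dependent; cluster
  *identities* across independent embeddings must be matched by marker
  profile, not by label. Exact reproduction of a published map requires the
  published embedding.
* Merge-order cutting is the honest generalisation of tree cutting to
  non-monotone constrained dendrograms, but it is not identical to a height
  cut when heights invert; both conventions appear in practice.
* The plug-in FDR is a point estimate with no small-sample guarantee; with
  16 permutable samples the p floor of the screen is ~1/12,870 per split
  pattern, and candidates near the cut-offs should be validated externally
  (the package provides the PC1 validation path for exactly that).
* The MANOVA partial variance shares are Pillai-based effect shares; they
  are comparable within a model, not across differently specified models.
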