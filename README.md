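# hexclust

Semi-automated gating of mass-cytometry (CyTOF) data by
**adjacency-constrained, marker-weighted complete-linkage clustering of
hexagonally binned 2-D embeddings**, with the downstream cohort statistics
that comparative immune-profiling studies need.

The package is aimed at analysts comparing immune phenotypes and functional
responses across cohorts (e.g. children sampled at several ages in two
locations, stimulated vs. unstimulated PBMCs) who want clusters that are
driven by the full marker panel but remain contiguous — and therefore
interpretable — on a t-SNE map.

## The method

1. **Prep** — asinh-transform (cofactor 5), QC (discard samples with
   < 3,000 cells), downsample 6,000 cells per sample, pool with an optional
   30,000-cell adult reference spike-in.
2. **Embed** — Barnes–Hut t-SNE (perplexity 60, theta 0.5, 2,000
   iterations), or any imported `(cell, x, y)` table.
3. **Hexbin** — tile the map with ~10,000 equal flat-top hexagons, drop
   empty bins, average each bin's member cells into a "bin expression"
   vector; bins sharing a border are adjacent, and an isolated bin gains one
   edge to its nearest non-empty neighbour.
4. **Cluster** — complete-linkage agglomeration on the weighted bin
   distance

   d(p,q) = sqrt( Σᵢ wᵢ (pᵢ − qᵢ)² )

   with the constraint that merging clusters must be adjacent on the map;
   when no adjacent pair remains the remaining merges are standard complete
   linkage. The tree is cut by merge order to k clusters, clusters below a
   1,500-cell floor are absorbed along the dendrogram, and cells inherit
   their bin's label.
5. **Stats** — per-sample cluster occupancy (fractions, rows sum to 1),
   stratified Mann–Whitney tests with per-stratum Benjamini–Hochberg
   correction, and PCA + type-II MANOVA (Pillai) variance partitioning over
   clinical covariates.
6. **Screen** — a permutation screen for functional markers associated with
   stunting (height-for-age z-score, HAZ): a two-sided standardized event
   criterion over groups (American reference / less stunted / more
   stunted), 5,000 HAZ permutations among Bangladeshi samples, plug-in FDR,
   PC1-based validation and Fisher combination of cohort p-values.

A synthetic-cohort generator with known ground truth
(`simulate_cohort()`, `simulate_feature_cohort()`) makes every stage
testable without any data download. See the methods vignette
(`vignettes/hexclust-methods.Rmd`) for the model, parameter meanings and
design decisions.

## Worked example

```r
library(hexclust)

mix <- default_mixture()                      # 23 markers, 8 populations
sim <- simulate_cohort(cohort_spec(n_donors = list(Bangladesh = 6, USA = 6),
                                   conditions = "unstim"),
                       mixture = mix, cells_per_sample = 500, seed = 42)
pooled <- pool_cells(sim$tables, seed = 42)
pooled
#> <cell_table> 6000 cells x 23 markers (12 samples; asinh-transformed)

emb   <- run_tsne(pooled, perplexity = 60, iterations = 1000, seed = 43)
grid  <- build_hexgrid(emb, target_bins = 1500)
graph <- build_adjacency(compute_bin_graph(grid, pooled))
graph
#> <bin_graph> 184 non-empty bins, 6000 cells, 417 edges

fit <- hex_adjclust(graph, sim$panel, k = 8, min_cells = 25)
fit$assignment
#> <cluster_assignment> 8 clusters over 184 bins; cell sizes 599, 1004, 480,
#>   966, 1290, 305, 870, 486

occ   <- compute_occupancy(fit$assignment$cell_cluster, pooled$sample_id,
                           k = fit$assignment$k)
tests <- test_occupancy(occ, sim$meta, group = "location", stratify = NULL)
head(tests[order(tests$fdr),
           c("cluster", "n_a", "n_b", "U", "ratio", "p_value", "fdr")], 4)
#>    cluster n_a n_b    U     ratio   p_value       fdr
#>  cluster_3   6   6 28.5 1.1621622 0.1055878 0.4347783
#>  cluster_5   6   6  7.5 0.8402282 0.1086946 0.4347783
#>  cluster_6   6   6 11.0 0.8711656 0.2928337 0.7808897
#>  cluster_1   6   6 16.5 1.0726644 0.8721134 0.8723368

truth <- unlist(sim$truth[names(sim$tables)], use.names = FALSE)
mclust::adjustedRandIndex(fit$assignment$cell_cluster, truth)
#> [1] 1
```

The 6,000 pooled cells land in 184 occupied hexagons; constrained complete
linkage cut at k = 8 recovers the eight generated populations exactly
(adjusted Rand index 1). No abundance effect was planted in this cohort, so
the occupancy ratios sit near 1 and no cluster clears the FDR threshold —
which is the correct answer here.

A command-line driver wrapping the same functions is installed at
`inst/cli/hexclust` (`simulate`, `run`, `screen` subcommands); `run`
executes prep → embed → cluster → stats (→ screen) and writes stage TSVs
plus a YAML run manifest with seeds, parameters and file hashes.

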