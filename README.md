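# cooccurnet

Statistical analysis of microbial community function from relative-abundance
feature tables, built around the question of how carbohydrate metabolism is
organized in wastewater-treatment sludge microbiomes: which
carbohydrate-active gene (CAG) families and taxonomic orders dominate, which
environmental factors (dissolved oxygen, temperature, salinity) structure
them, and which features co-occur or exclude each other across samples.

The package is aimed at microbiome researchers who have feature × sample
tables of relative abundances (here CAZy-style gene families and 16S-derived
taxonomic orders over nine sludge metagenomes) and want the full inferential
chain, reproducibly:

1. **Major-feature screen** — features present in at least half of the
   samples or reaching at least 1 % relative abundance are retained before
   any statistics (`filter_major_features()`).
2. **Ordination and group tests** — Bray–Curtis distances
   d(x, y) = Σᵢ|xᵢ−yᵢ| / Σᵢ(xᵢ+yᵢ), principal coordinate analysis, ANOSIM
   (R = (r̄_between − r̄_within)/(M/2) on distance ranks, permutation-tested
   with exact enumeration when feasible), and per-feature one-way ANOVA.
3. **Ordination concordance** — symmetric Procrustes superimposition of the
   gene-family and taxon ordinations; badness of fit
   M² = 1 − (Σ singular values)², tested by `protest()` with 10,000 row
   permutations.
4. **Robust co-occurrence network** — all-pairs Spearman correlations on the
   combined table; an edge is kept when r² > 0.6 and the
   Benjamini–Hochberg-adjusted p-value is below 0.05; the whole network is
   split into positive (co-occurrence) and negative (co-exclusion)
   sub-networks.
5. **Topology against an Erdős–Rényi null** — modularity (best-of-restarts
   Louvain), clustering coefficient, average path length over connected
   pairs, diameter, average degree 2m/n and density 2m/(n(n−1)), each
   compared with 10,000 G(n, m) random graphs of identical size; the
   CC/CC-random ratio with a near-1 path-length ratio diagnoses small-world
   structure, and per-module observed vs random co-occurrence incidence
   (100·n_c(n_c−1)/(n(n−1))) flags non-random module assembly.
6. **Synthetic data with known truth** — a Gaussian-copula generator plants
   correlation blocks, signed cross-block patterns and factor-linked shifts
   in compositional tables, so the entire pipeline can be validated end to
   end (`fixture_paper_shape()`, `generate_table()`).

## Worked example

```r
library(cooccurnet)
fx <- fixture_paper_shape(seed = 1)   # 46 gene families + 40 orders, 9 samples
fx$table
#> Abundance table: 86 features (46 gene_family, 40 taxon) x 9 samples [fraction]

dm <- bray_curtis(fx$table)
anosim(dm, fx$metadata$do_class, n_permutations = 10000, seed = 1)
#> ANOSIM: R = 0.3875, p = 0.03968 (exact, 126 permutations)

net <- build_network(spearman_all_pairs(fx$table), edge_criteria())
net
#> Co-occurrence network: 52 nodes, 137 edges
part <- louvain_best(net, restarts = 10, seed = 1)
topology_summary(net, part)
#> Topology (52 nodes, 137 edges): Q = 0.634, CC = 0.587, APL = 2.398,
#>   diameter = 6, AD = 5.269, density = 0.103

ens <- null_ensemble(n_nodes(net), n_edges(net), n_replicates = 1000, seed = 1)
cmp <- compare_to_null(topology_summary(net, part), ens)
subset(cmp, metric %in% c("modularity", "clustering_coefficient",
                          "average_path_length"))
#>                   metric  observed null_mean    null_sd     ratio         z
#> 1             modularity 0.6337312 0.3508851 0.01700487 1.8060929 16.633237
#> 2 clustering_coefficient 0.5868773 0.1006212 0.01893733 5.8325388 25.677116
#> 3    average_path_length 2.3979592 2.5083864 0.03174402 0.9559768 -3.478677
attr(cmp, "modular"); attr(cmp, "small_world")
#> [1] TRUE
#> [1] TRUE
```

Read: the aerobic/anaerobic contrast separates community profiles
(ANOSIM p < 0.05 under exact enumeration of all 126 label arrangements);
the inferred network is far more clustered (ratio 5.8, z ≈ 26) and more
modular than equally sized random graphs while keeping a random-like path
length (ratio 0.96) — the modular small-world signature.

## Analysis workflow

The `analysis/` scripts run the study's analysis sequence on a simulated
data set with known planted structure and write their tables under
`results/`:

```sh
Rscript analysis/01_simulate.R       # tables + metadata + ground truth
Rscript analysis/02_ordination.R     # PCoA, ANOSIM, ANOVA, Procrustes/protest
Rscript analysis/03_network.R        # robust Spearman network + hubs
Rscript analysis/04_topology_null.R  # topology, modules, 10,000-graph nulls
```

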