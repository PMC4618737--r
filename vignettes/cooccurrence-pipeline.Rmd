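---
title: "Methods: from abundance tables to co-occurrence network topology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from abundance tables to co-occurrence network topology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its statistical machinery: the
models and conventions each stage uses, the tunable parameters and their
defaults, what the synthetic-data generator does and does not emulate, and
the choices made where the underlying methods literature leaves room.

## The setting

The data are two relative-abundance tables over the same set of sludge
metagenome samples: carbohydrate-active gene (CAG) families annotated from
predicted genes, and taxonomic orders. Abundances are fractions of the
annotated genes/sequences per sample, so columns are compositions (sums at
most 1). The nine-sample design spans three binary-or-ternary environmental
factors — dissolved oxygen (aerobic/anaerobic), temperature class
(ambient/mesophilic/thermophilic) and salinity (fresh/saline) — and the
questions are (i) which factors structure the profiles, (ii) whether gene
content and taxonomy co-vary, and (iii) which feature pairs co-occur or
exclude each other beyond chance.

## Input handling

Tables are plain TSV (header cell `feature_id`, `.` decimals, no quoting);
the writer emits the identical dialect so read → write → read round-trips
bit-identically. Percent-scale tables are converted to fractions once at
load; every in-memory table carries unit `"fraction"` and is validated
(non-negative, finite, no duplicate ids, column sums ≤ 1 + 1e-9).

Technical or biological replicates are compared by ordinary least squares
of one replicate on the other *with* an intercept — the convention of
replicate scatterplots; regression through the origin is the main
alternative and would change the slope but not the qualitative
concordance judgement. A slope near 1 with R² near 1 indicates good
reproducibility; biological replicates are then collapsed by their
element-wise arithmetic mean under the source sample's label.

## The major-feature screen

`filter_config()` holds two thresholds: prevalence (detected in at least
half of the samples, `min_prevalence_fraction = 0.5`) and abundance
(reaching 1 %, `min_max_abundance = 0.01`). The natural-language rule
"present in less than half of the samples and below 1 %" is logically
ambiguous, so both readings are implemented. The default `AND_removal`
removes a feature only when it fails *both* criteria, which keeps
abundant-but-rare and ubiquitous-but-scarce features — the permissive
reading consistent with retaining a large major-feature set; `OR_removal`
is the strict alternative and always retains a subset of the default's
selection. "Abundance" is summarized per feature as the maximum across
samples by default (`abundance_stat = "max"`, again the permissive
reading); the mean is available. Filtering is idempotent and
order-preserving.

## Ordination and group tests

Bray–Curtis dissimilarity is computed by `vegan::vegdist()`; the one
convention added on top is that two all-zero samples are at distance 0
(vegan leaves 0/0 undefined). PCoA is the classical Gower double-centering
of −d²/2 followed by an eigendecomposition. Axes with non-positive
eigenvalues are reported with zero-width coordinate columns: negative
eigenvalues (Bray–Curtis is only a semimetric) stay visible in the
eigenvalue vector without distorting the configuration, and
`proportion_explained` is taken over the positive part only. On Euclidean
input the pairwise coordinate distances reproduce the input distances to
1e-8, which the test suite asserts.

ANOSIM uses the standard statistic R = (r̄_B − r̄_W)/(M/2) on the average
ranks of all M = n(n−1)/2 pairwise distances. Significance is by label
permutation with a twist worth making explicit: when the number of
*distinct* label arrangements (the multinomial coefficient) is at most
100,000, all of them are enumerated and the p-value is the exact
proportion of arrangements with R at least the observed one (the observed
labeling is itself in the enumeration, so p is never 0). Otherwise random
relabelings are drawn and p = (#{R\* ≥ R} + 1)/(N + 1). At the study's
design size (4 + 5 labels) the exact path always triggers — 126
arrangements — which is why the reported p-values are multiples of 1/126
and the seed is irrelevant there.

Per-feature screening uses the classical one-way ANOVA F test
(`stats::oneway.test`, equal variances). A feature with zero within-group
variance makes F unbounded; such fits are flagged `degenerate` with
`p_value = NA` rather than reporting p = 0.

## Procrustes concordance

Both ordinations are translated to their centroids, scaled to unit sum of
squares, and superimposed by the optimal orthogonal transformation from
the SVD of the cross-product matrix. Reflections are permitted (the full
orthogonal group), matching symmetric Procrustes practice. The badness of
fit is M² = 1 − (Σ singular values)², which equals the residual sum of
squared distances between matched samples. `protest()` permutes the row
order of the second configuration (10,000 permutations by default) and
reports p = (#{M²\* ≤ M²} + 1)/(N + 1). Both PCoA configurations enter
with all their axes, zero-padded to common width; restricting to the
first two axes is a plotting convention, not a testing one.

## The robust-edge network

All unordered feature pairs of the combined (gene family + taxon) table
are tested — family–family, taxon–taxon and family–taxon alike. Spearman's
rho uses average ranks for ties; p-values default to the t approximation
t = ρ√((n−2)/(1−ρ²)), with an exact permutation null available for small
sample counts (all n! orderings, n ≤ 9). Constant features cannot be
ranked informatively and are skipped with a warning rather than an error.

Retention applies two rules jointly: strength and significance.
The strength rule is read literally as the *squared* coefficient
exceeding 0.6, i.e. |ρ| > 0.775 (`threshold_on = "rho2"`); the laxer
|ρ| > 0.6 reading is selectable because both appear in common use.
Significance applies Benjamini–Hochberg (the standard choice for
correlation screens; Bonferroni selectable) jointly over *all* tested
pairs, with adjusted p below 0.05 by default — 0.05 being the
methods-level threshold; a stricter 0.01 is sometimes quoted in display
captions and is one config value away. The node set of the resulting
network is the set of features incident to at least one retained edge,
and the positive/negative sub-networks recompute their node sets from
their own edges, so a feature correlated positively with one partner and
negatively with another appears in both.

## Topology, modules, incidence

Six properties summarize each network: modularity of the supplied
partition, clustering coefficient, average path length, diameter, average
degree 2m/n, and density 2m/(n(n−1)).

Two conventions deserve emphasis because the networks involved are
disconnected and sparse:

* **Paths.** Average path length is the mean shortest-path length over
  *connected* pairs only, and the diameter is the longest *finite*
  shortest path (the maximum within components). With infinite-distance
  conventions every disconnected graph — including most G(n, m) null
  replicates at these densities — would report infinity.
* **Clustering.** The default clustering coefficient is the global
  transitivity ratio (3 × triangles / connected triples), the default of
  the igraph toolchain in which these topology suites are conventionally
  computed; its G(n, m) ensemble mean is the edge density to within
  Monte-Carlo error, which is what the published null rows reflect. The
  average-local convention (mean local clustering over nodes of degree
  ≥ 2, `cc_type = "local_mean"`) is also implemented; both report 0 for
  triangle-free graphs such as the co-exclusion network, and the test
  suite checks the conventions agree on clique and triangle-free cases.

Modules come from igraph's Louvain (multi-level greedy modularity)
implementation. Louvain is traversal-order-dependent, so
`louvain_partition()` permutes the vertex order by a seed, and
`louvain_best()` runs 10 seeded restarts, keeps the best-Q partition and
records all Q values. The returned Q is *recomputed* from the assignment
with the package's own Newman–Girvan formula Q = Σ_c (e_c/m − (d_c/2m)²),
and equality with igraph's modularity is asserted on every test graph —
an implementation/oracle cross-check, not a tautology.

Per-module co-occurrence incidence is the percentage of the network's
edges that fall inside the module, compared with the random-association
expectation 100·n_c(n_c−1)/(n(n−1)) given the module sizes; modules with
observed above random are flagged as non-randomly assembled.

## The Erdős–Rényi null

The null is G(n, m) — m edges sampled uniformly without replacement —
*not* G(n, p), because the comparison fixes both node and edge counts.
Each of the 10,000 replicates gets its topology summary with one Louvain
run (not best-of-restarts: the ensemble mean should reflect a typical
run, and a per-replicate search would bias Q upward); per-replicate seeds
are derived from the master seed by a counter, so the ensemble summary is
bit-reproducible. Density is fixed by construction (sd exactly 0), and
average degree likewise; the interesting rows are modularity, clustering,
path length and diameter. `compare_to_null()` reports per-metric ratios
and z-scores (z is left undefined when the null sd is 0), flags
"modular" when both modularity and clustering exceed their null means,
and "small-world" when the clustering ratio is at least 2 while the
average-path-length ratio stays within 25 % of 1 — thresholds chosen
as a conservative reading of "high clustering at near-random path
length"; the flag is descriptive, no test depends on it.

## The synthetic-data generator

The generator exists so every stage can be validated against known truth
without the study's raw data. It draws a latent multivariate normal with
a block correlation structure — within-block correlation ρ for planted
modules, signed cross-block correlation for planted co-exclusion — maps
each feature through its monotone Gaussian-copula transform to a
log-normal marginal, applies multiplicative group effects (e.g. an
aerobic-associated block amplified in aerobic samples) and finally closes
each sample to fractions. The copula construction is essential: the
pipeline is rank-based, and monotone marginal transforms preserve ranks
exactly, so a latent correlation ρ maps to a known Spearman correlation
(6/π)·asin(ρ/2) — asserted in the tests at large n. If the requested
block structure is not positive semidefinite it is repaired to the
nearest PSD correlation matrix (`Matrix::nearPD`), and generation fails
when the repair moves any entry by more than 0.1 — a planted structure
that far from feasible should be redesigned, not silently distorted.

Closure is the one step that breaks exact rank invariance: dividing by
the per-sample total induces spurious (typically negative) correlation.
The generator measures this on every draw and reports it as
`closure_shift`, the mean change of off-diagonal Spearman correlations
caused by closure; `closure = FALSE` is available when exact rank
preservation is wanted.

The ready-made `fixture_paper_shape()` mirrors the study's shape: 46 gene
families and 40 taxonomic orders over the nine-sample design (4 aerobic /
5 anaerobic, A/M/T temperature, fresh/saline). It plants three positive
modules mixing both feature kinds, ties two of them to the
dissolved-oxygen contrast (×3 shifts), and adds an aerobic/anaerobic
block pair with strong opposing shifts (×8) and latent cross-correlation
−0.8 — the co-exclusion pattern. These effect sizes were chosen so the
simulated data exhibit the qualitative regime of interest at n = 9:
dissolved oxygen separates the profiles at ANOSIM p < 0.05 while
salinity does not, the inferred network has on the order of 50 nodes with
both edge signs, and the co-exclusion sub-network is triangle-free. What
the generator does *not* emulate: sequencing and annotation noise,
rarefaction effects, compositional zeros (log-normal marginals are
strictly positive), phylogenetic correlation among taxa, and any
sequence-level process. Passing recovery tests on these tables therefore
demonstrates the statistical machinery, not robustness to upstream
bioinformatics error.

Two regimes are used deliberately. The default n = 9 mirrors the study
and is honest about its power: at |ρ| > 0.775 with BH correction over
3,655 pairs, only part of the planted structure is recoverable.
Recovery benchmarks use n = 60 with within-block latent ρ = 0.95, where
the default criteria recover ≥ 80 % of planted edges, Louvain matches the
planted blocks (adjusted Rand ≥ 0.9), and null tables yield essentially
no edges (false-edge proportion below 1 %).

## Numerical and reproducibility choices

* Permutation p-values use the +1 correction on the sampling path and
  exact proportions (observed labeling included) on the enumeration path;
  neither can return 0.
* Floating-point ties in permutation statistics are compared with a
  1e-12 tolerance so exact re-achievements of the observed statistic
  count as ties.
* Every stochastic operation takes an explicit seed; pipeline runs write
  a manifest (resolved configuration + seed + file list, deliberately no
  timestamps) from which any run can be reproduced bit-identically.
* Degenerate inputs have defined behavior rather than NaN: all-zero
  sample pairs at Bray–Curtis 0, all-zero distance matrices giving
  all-zero ordinations, triple-free graphs at clustering 0, edgeless
  networks rejected where modularity or incidence would be undefined.
* Ensemble sizes in the test suite are precision-driven: wide ±3-sd
  checks use 500 replicates, while the clustering-ratio check uses 2,500
  so the ensemble mean is resolved well inside its two-decimal rounding
  bin; the acceptance script uses the full 10,000.

## Known limitations

* Spearman screening on compositions ignores compositional coupling; the
  generator quantifies the closure-induced bias, but no SparCC-style
  correction is applied — by design, to match the analysis being
  reproduced.
* With nine samples the t-approximate Spearman p-values are coarse, and
  the discrete exact ANOSIM p floor (1/126 for the 4+5 design) limits
  attainable significance.
* The published network node/edge counts are reported inconsistently
  across the source's own sections (165 vs 153 vs 156 edges for the whole
  network); the topology identities here follow the tabulated 68/165,
  53/75 and 56/90, and nothing in the package attempts to resolve the
  discrepancy.
* Louvain is a heuristic: best-of-10 restarts stabilizes but does not
  guarantee the optimal partition.
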