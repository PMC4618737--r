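#!/usr/bin/env Rscript

# Step 2 — community structure and its drivers.
#
# Both profiles (CAG families, taxonomic orders) are screened for major
# features, compared between samples with Bray-Curtis distances and PCoA,
# and tested for separation along the three environmental factors
# (dissolved oxygen, temperature class, salinity) by ANOSIM; individual
# features are screened by one-way ANOVA.  Finally the two ordinations
# are superimposed by symmetric Procrustes analysis and the concordance
# is tested with 10,000 row permutations (protest).

suppressMessages(library(cooccurnet))

seed <- 1
out <- "results/ordination"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cag <- read_abundance_table("results/data/cag_table.tsv",
                            feature_kind = "gene_family")
tax <- read_abundance_table("results/data/taxon_table.tsv",
                            feature_kind = "taxon")
md <- read_sample_metadata("results/data/metadata.tsv")

filt <- list(cag = filter_major_features(cag), taxon = filter_major_features(tax))
cat(sprintf("Major features: %d / %d CAG families, %d / %d orders\n",
            nrow(filt$cag$values), nrow(cag$values),
            nrow(filt$taxon$values), nrow(tax$values)))

dists <- lapply(filt, bray_curtis)
ords <- lapply(dists, pcoa)
for (nm in names(ords)) {
  pe <- ords[[nm]]$proportion_explained
  cat(sprintf("%s PCoA: axis 1 %.1f %%, axis 2 %.1f %% of positive inertia\n",
              nm, 100 * pe[1], 100 * pe[2]))
  utils::write.table(
    data.frame(sample_id = rownames(ords[[nm]]$coordinates),
               ords[[nm]]$coordinates[, 1:4]),
    file.path(out, sprintf("pcoa_%s.tsv", nm)),
    sep = "\t", quote = FALSE, row.names = FALSE)
}

factors <- c("do_class", "temperature_class", "salinity_class")
rows <- list()
for (nm in names(dists)) for (fc in factors) {
  a <- anosim(dists[[nm]], md[[fc]], n_permutations = 10000, seed = seed)
  cat(sprintf("ANOSIM %-6s ~ %-18s R = %+.3f  p = %.4f (%s)\n",
              nm, fc, a$r_statistic, a$p_value, a$method))
  rows[[paste(nm, fc)]] <- data.frame(
    profile = nm, factor = fc, r_statistic = a$r_statistic,
    p_value = a$p_value, n_permutations = a$n_permutations,
    method = a$method)
}
utils::write.table(do.call(rbind, c(rows, list(make.row.names = FALSE))),
                   file.path(out, "anosim.tsv"),
                   sep = "\t", quote = FALSE, row.names = FALSE)

# per-feature one-way ANOVA along DO, BH-adjusted within each profile
for (nm in names(filt)) {
  v <- filt[[nm]]$values
  res <- lapply(seq_len(nrow(v)), function(i) one_way_anova(v[i, ], md$do_class))
  p <- vapply(res, `[[`, numeric(1), "p_value")
  tab <- data.frame(feature_id = rownames(v),
                    f_statistic = vapply(res, `[[`, numeric(1), "f_statistic"),
                    p_value = p,
                    p_adj = adjust_pvalues(p))
  cat(sprintf("ANOVA (DO) on %s: %d features with BH-adjusted p < 0.05\n",
              nm, sum(tab$p_adj < 0.05, na.rm = TRUE)))
  utils::write.table(tab, file.path(out, sprintf("anova_do_%s.tsv", nm)),
                     sep = "\t", quote = FALSE, row.names = FALSE)
}

conc <- protest(ords$cag$coordinates, ords$taxon$coordinates,
                n_permutations = 10000, seed = seed)
cat(sprintf("Procrustes CAG vs taxa: M^2 = %.4f, p = %.4f (%d permutations)\n",
            conc$m_squared, conc$p_value, conc$n_permutations))
utils::write.table(
  data.frame(m_squared = conc$m_squared, p_value = conc$p_value,
             n_permutations = conc$n_permutations),
  file.path(out, "procrustes.tsv"), sep = "\t", quote = FALSE,
  row.names = FALSE)
cat("Wrote", out, "\n")
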