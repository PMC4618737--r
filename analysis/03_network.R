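#!/usr/bin/env Rscript

# Step 3 — robust Spearman co-occurrence network.
#
# All pairwise Spearman correlations between the major CAG families and
# taxonomic orders are screened with the robust-edge rule (squared
# coefficient above 0.6 and Benjamini-Hochberg adjusted p below 0.05).
# The retained whole network is split into positive (co-occurrence) and
# negative (co-exclusion) sub-networks, and the highest-degree nodes are
# reported as candidate hubs.

suppressMessages(library(cooccurnet))

out <- "results/network"
dir.create(out, recursive = TRUE, showWarnings = FALSE)

cag <- read_abundance_table("results/data/cag_table.tsv",
                            feature_kind = "gene_family")
tax <- read_abundance_table("results/data/taxon_table.tsv",
                            feature_kind = "taxon")
combined <- combine_features(filter_major_features(cag),
                             filter_major_features(tax))

edges <- spearman_all_pairs(combined)
cat(sprintf("Tested %d feature pairs across %d features\n",
            nrow(edges), nrow(combined$values)))

net <- build_network(edges, edge_criteria())
subs <- split_by_sign(net)
cat(sprintf("Whole network: %d nodes, %d edges (%d positive, %d negative)\n",
            n_nodes(net), n_edges(net),
            n_edges(subs$positive), n_edges(subs$negative)))
cat(sprintf("Positive sub-network: %d nodes; negative: %d nodes\n",
            n_nodes(subs$positive), n_nodes(subs$negative)))

write_edge_list(net, file.path(out, "edges_whole.tsv"))
write_network_graphml(net, file.path(out, "network_whole.graphml"))
for (nm in c("positive", "negative")) {
  if (n_edges(subs[[nm]]) > 0)
    write_network_graphml(subs[[nm]],
                          file.path(out, sprintf("network_%s.graphml", nm)))
}

hubs <- hub_nodes(net, 8)
cat("Top-degree nodes (candidate hubs):\n")
for (i in seq_len(nrow(hubs)))
  cat(sprintf("  %-8s %-12s degree %d\n", hubs$id[i], hubs$kind[i],
              hubs$degree[i]))
utils::write.table(hubs, file.path(out, "hubs.tsv"), sep = "\t",
                   quote = FALSE, row.names = FALSE)
cat("Wrote", out, "\n")
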