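#' End-to-end pipeline configuration
#'
#' Gathers every tunable of the analysis: the major-feature screen, the
#' robust-edge criteria, permutation and null-ensemble sizes, the Louvain
#' restart count and the master seed.  The resolved configuration is
#' serialized into the run manifest so any run can be reproduced from its
#' outputs alone.
#'
#' @param filter a [filter_config()].
#' @param criteria an [edge_criteria()].
#' @param n_permutations permutations for ANOSIM and protest
#'   (default 10000).
#' @param null_replicates Erdos-Renyi ensemble size (default 10000).
#' @param louvain_restarts seeded Louvain restarts (default 10).
#' @param cc_type clustering-coefficient convention, see
#'   [topology_summary()].
#' @param seed master seed for every stochastic stage.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(filter = filter_config(),
                            criteria = edge_criteria(),
                            n_permutations = 10000,
                            null_replicates = 10000,
                            louvain_restarts = 10,
                            cc_type = c("global", "local_mean"),
                            seed = 1) {
  cc_type <- match.arg(cc_type)
  stopifnot(inherits(filter, "filter_config"),
            inherits(criteria, "edge_criteria"),
            n_permutations >= 1, null_replicates >= 2,
            louvain_restarts >= 1)
  structure(list(filter = filter, criteria = criteria,
                 n_permutations = n_permutations,
                 null_replicates = null_replicates,
                 louvain_restarts = louvain_restarts,
                 cc_type = cc_type, seed = seed),
            class = "pipeline_config")
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full analysis on a gene-family / taxon table pair
#'
#' Orchestrates every stage: major-feature filtering of both tables,
#' Bray-Curtis distances and PCoA ordinations, ANOSIM per environmental
#' factor on both profiles, per-feature one-way ANOVA per factor,
#' Procrustes concordance between the two ordinations with a protest
#' permutation test, the all-pairs Spearman screen on the combined table,
#' robust-edge network construction with positive/negative sub-networks,
#' Louvain modules, topology summaries, module co-occurrence incidence,
#' Erdos-Renyi null ensembles with observed-vs-null comparison, hub
#' ranking, and a machine-readable manifest.  All outputs are TSV/GraphML/
#' JSON files under `out_dir`; reruns with the same configuration are
#' bit-identical.
#'
#' @param cag_table gene-family [abundance_table()] (unfiltered).
#' @param taxon_table taxon [abundance_table()] (unfiltered).
#' @param metadata sample metadata data frame covering both tables'
#'   samples (see [validate_sample_metadata()]).
#' @param config a [pipeline_config()].
#' @param out_dir output directory, created if missing.
#' @return Invisibly, a list with all intermediate objects (`filtered`,
#'   `distances`, `ordinations`, `anosim`, `anova`, `procrustes`,
#'   `edges`, `networks`, `partitions`, `topology`, `incidence`,
#'   `null_comparisons`, `hubs`, `manifest`).
#' @export
run_all <- function(cag_table, taxon_table, metadata,
                    config = pipeline_config(), out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  metadata <- validate_sample_metadata(metadata)
  samples <- sample_ids(cag_table)
  offenders <- unique(c(
    setdiff(samples, metadata$sample_id),
    setdiff(sample_ids(taxon_table), metadata$sample_id),
    setdiff(symdiff_chr(samples, sample_ids(taxon_table)), character(0))))
  if (length(offenders))
    stop("sample mismatch between tables and metadata: ",
         paste(offenders, collapse = ", "))
  metadata <- metadata[match(samples, metadata$sample_id), , drop = FALSE]
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pathto <- function(f) file.path(out_dir, f)
  files <- character(0)
  keep_file <- function(f) files[[length(files) + 1L]] <<- f

  ## 1. major-feature screen
  filt <- list(cag = filter_major_features(cag_table, config$filter),
               taxon = filter_major_features(taxon_table, config$filter))
  keep_file(write_abundance_table(filt$cag, pathto("filtered_cag.tsv")))
  keep_file(write_abundance_table(filt$taxon, pathto("filtered_taxon.tsv")))

  ## 2. distances + ordinations
  dists <- lapply(filt, bray_curtis)
  ords <- lapply(dists, pcoa)
  for (nm in names(dists)) {
    keep_file(write_tsv(data.frame(sample_id = rownames(dists[[nm]]),
                                   as.data.frame(unclass(dists[[nm]]))),
                        pathto(sprintf("braycurtis_%s.tsv", nm))))
    keep_file(write_tsv(data.frame(sample_id = rownames(ords[[nm]]$coordinates),
                                   as.data.frame(ords[[nm]]$coordinates)),
                        pathto(sprintf("pcoa_%s.tsv", nm))))
  }

  ## 3. group-separation tests
  factors <- c("do_class", "temperature_class", "salinity_class")
  anosim_rows <- list()
  for (nm in names(dists)) for (fc in factors) {
    res <- anosim(dists[[nm]], metadata[[fc]],
                  n_permutations = config$n_permutations,
                  seed = config$seed)
    anosim_rows[[paste(nm, fc)]] <-
      data.frame(profile = nm, factor = fc, r_statistic = res$r_statistic,
                 p_value = res$p_value, n_permutations = res$n_permutations,
                 method = res$method, stringsAsFactors = FALSE)
  }
  anosim_tab <- do.call(rbind, c(anosim_rows, list(make.row.names = FALSE)))
  keep_file(write_tsv(anosim_tab, pathto("anosim.tsv")))

  anova_rows <- list()
  for (nm in names(filt)) for (fc in factors) {
    v <- filt[[nm]]$values
    res <- lapply(seq_len(nrow(v)),
                  function(i) one_way_anova(v[i, ], metadata[[fc]]))
    p <- vapply(res, `[[`, numeric(1), "p_value")
    ok <- !is.na(p)
    p_adj <- rep(NA_real_, length(p))
    p_adj[ok] <- adjust_pvalues(p[ok], config$criteria$correction_method)
    anova_rows[[paste(nm, fc)]] <- data.frame(
      profile = nm, factor = fc, feature_id = rownames(v),
      f_statistic = vapply(res, `[[`, numeric(1), "f_statistic"),
      p_value = p, p_adj = p_adj,
      degenerate = vapply(res, `[[`, logical(1), "degenerate"),
      stringsAsFactors = FALSE)
  }
  anova_tab <- do.call(rbind, c(anova_rows, list(make.row.names = FALSE)))
  keep_file(write_tsv(anova_tab, pathto("anova.tsv")))

  ## 4. ordination concordance
  conc <- protest(ords$cag$coordinates, ords$taxon$coordinates,
                  n_permutations = config$n_permutations,
                  seed = config$seed)
  keep_file(write_tsv(data.frame(m_squared = conc$m_squared,
                                 p_value = conc$p_value,
                                 n_permutations = conc$n_permutations),
                      pathto("procrustes.tsv")))
  keep_file(write_tsv(data.frame(sample_id = names(conc$per_sample_residuals),
                                 residual = conc$per_sample_residuals),
                      pathto("procrustes_residuals.tsv")))

  ## 5. network inference
  combined <- combine_features(filt$cag, filt$taxon)
  edges <- spearman_all_pairs(combined, seed = config$seed)
  whole <- build_network(edges, config$criteria)
  subs <- split_by_sign(whole)
  nets <- list(whole = whole, positive = subs$positive,
               negative = subs$negative)
  keep_file(write_tsv(whole$edges, pathto("edges_whole.tsv")))
  for (nm in names(nets)) {
    if (n_edges(nets[[nm]]) > 0)
      keep_file(write_network_graphml(nets[[nm]],
                                      pathto(sprintf("network_%s.graphml", nm))))
  }

  ## 6. modules, topology, nulls
  partitions <- list()
  topo <- list()
  incidence <- list()
  comparisons <- list()
  topo_rows <- list()
  for (nm in names(nets)) {
    net <- nets[[nm]]
    if (n_edges(net) == 0L) next
    part <- louvain_best(net, restarts = config$louvain_restarts,
                         seed = config$seed)
    ts <- topology_summary(net, part, cc_type = config$cc_type)
    ens <- null_ensemble(n_nodes(net), n_edges(net),
                         n_replicates = config$null_replicates,
                         seed = config$seed, cc_type = config$cc_type)
    partitions[[nm]] <- part
    topo[[nm]] <- ts
    incidence[[nm]] <- module_incidence(net, part)
    comparisons[[nm]] <- compare_to_null(ts, ens)
    topo_rows[[nm]] <- data.frame(
      network = nm, n_nodes = ts$n_nodes, n_edges = ts$n_edges,
      modularity = ts$modularity,
      clustering_coefficient = ts$clustering_coefficient,
      average_path_length = ts$average_path_length, diameter = ts$diameter,
      average_degree = ts$average_degree, density = ts$density,
      stringsAsFactors = FALSE)
    keep_file(write_tsv(data.frame(node = names(part$assignment),
                                   module = part$assignment),
                        pathto(sprintf("modules_%s.tsv", nm))))
    keep_file(write_tsv(incidence[[nm]],
                        pathto(sprintf("incidence_%s.tsv", nm))))
    keep_file(write_tsv(cbind(network = nm, comparisons[[nm]]),
                        pathto(sprintf("null_comparison_%s.tsv", nm))))
  }
  if (length(topo_rows))
    keep_file(write_tsv(do.call(rbind, c(topo_rows,
                                         list(make.row.names = FALSE))),
                        pathto("topology.tsv")))
  hubs <- if (n_edges(whole)) hub_nodes(whole, min(10, n_nodes(whole)))
          else NULL
  if (!is.null(hubs)) keep_file(write_tsv(hubs, pathto("hubs.tsv")))

  ## 7. manifest (no timestamps: reruns must be bit-identical)
  manifest <- list(
    package = "cooccurnet",
    version = as.character(utils::packageVersion("cooccurnet")),
    seed = config$seed,
    config = list(
      min_prevalence_fraction = config$filter$min_prevalence_fraction,
      min_max_abundance = config$filter$min_max_abundance,
      combine_rule = config$filter$combine_rule,
      abundance_stat = config$filter$abundance_stat,
      rho_squared_min = config$criteria$rho_squared_min,
      p_adj_max = config$criteria$p_adj_max,
      correction_method = config$criteria$correction_method,
      threshold_on = config$criteria$threshold_on,
      n_permutations = config$n_permutations,
      null_replicates = config$null_replicates,
      louvain_restarts = config$louvain_restarts,
      cc_type = config$cc_type),
    files = sort(basename(unlist(files))))
  jsonlite::write_json(manifest, pathto("manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(filtered = filt, distances = dists, ordinations = ords,
                 anosim = anosim_tab, anova = anova_tab, procrustes = conc,
                 edges = edges, networks = nets, partitions = partitions,
                 topology = topo, incidence = incidence,
                 null_comparisons = comparisons, hubs = hubs,
                 manifest = manifest))
}

symdiff_chr <- function(a, b) union(setdiff(a, b), setdiff(b, a))
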