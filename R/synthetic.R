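#' Specification of a synthetic abundance data set
#'
#' Describes a Gaussian-copula generator for compositional abundance
#' tables with planted structure: blocks of features sharing a latent
#' within-block correlation (the planted modules), signed cross-block
#' correlations (planted co-exclusion when negative), log-normal marginal
#' abundances, and multiplicative group effects tied to sample metadata
#' factors.  Because the downstream pipeline is rank-based, the copula
#' construction guarantees the planted rank correlations survive the
#' marginal transforms.
#'
#' @param n_samples number of samples (default 9, the study design size);
#'   at least 4.
#' @param blocks list of blocks, each a list with `id`, `n_gene_family`,
#'   `n_taxon` and `rho` (latent within-block correlation; 0 for
#'   background features).
#' @param cross_block optional data frame with columns `a`, `b`, `rho`
#'   giving a signed latent correlation applied to every feature pair
#'   between blocks `a` and `b`.
#' @param meanlog,sdlog log-normal marginal parameters, recycled over
#'   features.
#' @param group_effects optional list of effects, each a list with
#'   `factor` (a metadata column), `level`, `blocks` (block ids) and
#'   `multiplier`: abundances of those blocks are multiplied in samples of
#'   that level, before closure.
#' @param closure close each sample to fractions summing to 1 (default
#'   `TRUE`).  Closure is what real relative-abundance tables undergo, but
#'   it perturbs ranks through the shared denominator; setting `FALSE`
#'   yields the raw log-normal draws, for which the planted rank
#'   correlations hold exactly.
#' @param metadata optional sample metadata data frame; defaults to the
#'   nine-sample wastewater design (4 aerobic / 5 anaerobic; temperature
#'   A/M/T; fresh/saline) when `n_samples` is 9, otherwise to a balanced
#'   aerobic/anaerobic split.
#' @param seed integer seed; generation is deterministic given the spec.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_samples = 9, blocks, cross_block = NULL,
                           meanlog = log(0.01), sdlog = 1,
                           group_effects = NULL, closure = TRUE,
                           metadata = NULL, seed = 1) {
  if (n_samples < 4) stop("`n_samples` must be at least 4")
  ids <- vapply(blocks, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate block ids")
  if (!is.null(cross_block)) {
    stopifnot(all(c("a", "b", "rho") %in% names(cross_block)))
    if (!all(c(cross_block$a, cross_block$b) %in% ids))
      stop("cross_block refers to unknown block ids")
  }
  if (is.null(metadata)) metadata <- default_sample_design(n_samples)
  metadata <- validate_sample_metadata(metadata)
  if (nrow(metadata) != n_samples)
    stop("metadata must describe exactly `n_samples` samples")
  structure(list(n_samples = n_samples, blocks = blocks,
                 cross_block = cross_block, meanlog = meanlog,
                 sdlog = sdlog, group_effects = group_effects,
                 closure = closure, metadata = metadata, seed = seed),
            class = "synthetic_spec")
}

## Nine-sample wastewater-treatment design (activated sludge + digesters):
## 4 aerobic / 5 anaerobic, ambient/mesophilic/thermophilic, fresh/saline.
default_sample_design <- function(n_samples) {
  if (n_samples == 9) {
    data.frame(
      sample_id = sprintf("S%d", 1:9),
      do_class = c(rep("aerobic", 4), rep("anaerobic", 5)),
      temperature_class = c("A", "A", "A", "A", "M", "M", "M", "T", "T"),
      salinity_class = c("fresh", "fresh", "saline", "saline", "saline",
                         "fresh", "saline", "saline", "fresh"),
      stringsAsFactors = FALSE)
  } else {
    half <- ceiling(n_samples / 2)
    data.frame(
      sample_id = sprintf("S%d", seq_len(n_samples)),
      do_class = c(rep("aerobic", half), rep("anaerobic", n_samples - half)),
      temperature_class = rep_len(c("A", "M", "T"), n_samples),
      salinity_class = rep_len(c("fresh", "saline"), n_samples),
      stringsAsFactors = FALSE)
  }
}

synthetic_feature_frame <- function(spec) {
  do.call(rbind, lapply(spec$blocks, function(b) {
    n_gf <- b$n_gene_family
    n_tx <- b$n_taxon
    data.frame(block = b$id,
               kind = c(rep("gene_family", n_gf), rep("taxon", n_tx)),
               rho = b$rho, stringsAsFactors = FALSE)
  }))
}

#' Generate a synthetic abundance table with known ground truth
#'
#' Draws a latent multivariate normal with the block correlation matrix
#' (repaired to the nearest positive-semidefinite correlation matrix when
#' needed), maps each feature through a monotone transform to its
#' log-normal marginal, applies the multiplicative group effects, and
#' closes each sample to fractions summing to 1.
#'
#' @param spec a [synthetic_spec()].
#' @param psd_tol maximum entry-wise deviation tolerated between the
#'   requested correlation matrix and its nearest-PSD repair.
#' @return A list with `table` (an [abundance_table()]), `metadata`,
#'   `truth` — the planted `edges` (data frame `feature_a`, `feature_b`,
#'   `sign`), `modules` (block id per feature; `NA` for rho-0 background
#'   blocks) and `labels` (the metadata) — and `closure_shift`, the mean
#'   change of off-diagonal Spearman correlations introduced by closure
#'   (`NA` when closure is disabled).
#' @export
generate_table <- function(spec, psd_tol = 0.1) {
  stopifnot(inherits(spec, "synthetic_spec"))
  feats <- synthetic_feature_frame(spec)
  p <- nrow(feats)
  gf <- feats$kind == "gene_family"
  feats$id <- NA_character_
  feats$id[gf] <- sprintf("GF%03d", seq_len(sum(gf)))
  feats$id[!gf] <- sprintf("TX%03d", seq_len(sum(!gf)))
  sigma <- diag(p)
  for (b in spec$blocks) {
    i <- which(feats$block == b$id)
    if (length(i) > 1 && b$rho != 0)
      sigma[i, i] <- b$rho + (1 - b$rho) * diag(length(i))
  }
  if (!is.null(spec$cross_block)) {
    for (r in seq_len(nrow(spec$cross_block))) {
      i <- which(feats$block == spec$cross_block$a[r])
      j <- which(feats$block == spec$cross_block$b[r])
      sigma[i, j] <- spec$cross_block$rho[r]
      sigma[j, i] <- spec$cross_block$rho[r]
    }
  }
  ev_min <- min(eigen(sigma, symmetric = TRUE, only.values = TRUE)$values)
  if (ev_min < -1e-10) {
    rep_m <- as.matrix(Matrix::nearPD(sigma, corr = TRUE)$mat)
    if (max(abs(rep_m - sigma)) > psd_tol)
      stop("planted correlation structure is too far from positive ",
           "semidefinite (nearest-PSD repair moved an entry by more than ",
           psd_tol, ")")
    sigma <- rep_m
  }
  cl <- chol(sigma + diag(1e-10, p))
  set.seed(spec$seed)
  z <- matrix(stats::rnorm(spec$n_samples * p), spec$n_samples, p) %*% cl
  meanlog <- rep_len(spec$meanlog, p)
  sdlog <- rep_len(spec$sdlog, p)
  x <- stats::qlnorm(stats::pnorm(z), rep(meanlog, each = spec$n_samples),
                     rep(sdlog, each = spec$n_samples))
  for (ge in spec$group_effects %||% list()) {
    rows <- spec$metadata[[ge$factor]] == ge$level
    cols <- feats$block %in% ge$blocks
    x[rows, cols] <- x[rows, cols] * ge$multiplier
  }
  closure_shift <- NA_real_
  if (isTRUE(spec$closure %||% TRUE)) {
    pre <- stats::cor(x, method = "spearman")
    x <- x / rowSums(x)  # closure to compositions
    post <- stats::cor(x, method = "spearman")
    off <- upper.tri(pre)
    # spurious (typically negative) correlation induced by the shared
    # denominator, reported so null analyses can budget for it
    closure_shift <- mean(post[off] - pre[off])
  } else {
    x <- x / max(rowSums(x))  # common rescale keeps columns <= 1, ranks intact
  }
  vals <- t(x)
  rownames(vals) <- feats$id
  colnames(vals) <- spec$metadata$sample_id
  table <- abundance_table(vals, feature_kinds = feats$kind,
                           unit = "fraction")
  truth <- list(edges = planted_edges(feats, spec$cross_block),
                modules = stats::setNames(
                  ifelse(feats$rho != 0, feats$block, NA_character_),
                  feats$id),
                labels = spec$metadata)
  list(table = table, metadata = spec$metadata, truth = truth,
       closure_shift = closure_shift)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

planted_edges <- function(feats, cross_block) {
  out <- list()
  for (b in unique(feats$block)) {
    i <- which(feats$block == b)
    if (length(i) > 1 && feats$rho[i[1]] > 0) {
      pr <- utils::combn(feats$id[i], 2)
      out[[length(out) + 1L]] <-
        data.frame(feature_a = pr[1L, ], feature_b = pr[2L, ],
                   sign = "positive", stringsAsFactors = FALSE)
    }
  }
  if (!is.null(cross_block)) {
    for (r in seq_len(nrow(cross_block))) {
      i <- feats$id[feats$block == cross_block$a[r]]
      j <- feats$id[feats$block == cross_block$b[r]]
      pr <- expand.grid(feature_a = i, feature_b = j,
                        stringsAsFactors = FALSE)
      pr$sign <- if (cross_block$rho[r] > 0) "positive" else "negative"
      out[[length(out) + 1L]] <- pr
    }
  }
  if (!length(out))
    return(data.frame(feature_a = character(), feature_b = character(),
                      sign = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Synthetic fixture shaped like the sludge study
#'
#' 46 gene families and 40 taxonomic orders across 9 samples: three
#' planted positive modules mixing both feature kinds (two of them tied
#' to the dissolved-oxygen contrast, echoing aerobic- and
#' anaerobic-associated hub modules), one planted negative (co-exclusion)
#' pattern between an aerobic-associated and an anaerobic-associated
#' block with strong opposing DO-linked abundance shifts, and rho-0
#' background features.  Columns close to 1.
#'
#' @param seed integer seed.
#' @return As [generate_table()].
#' @export
fixture_paper_shape <- function(seed = 1) {
  blocks <- list(
    list(id = "M1", n_gene_family = 8, n_taxon = 4, rho = 0.85),
    list(id = "M2", n_gene_family = 7, n_taxon = 4, rho = 0.85),
    list(id = "M3", n_gene_family = 6, n_taxon = 4, rho = 0.85),
    list(id = "AE", n_gene_family = 5, n_taxon = 5, rho = 0.8),
    list(id = "AN", n_gene_family = 5, n_taxon = 5, rho = 0.8),
    list(id = "BG", n_gene_family = 15, n_taxon = 18, rho = 0))
  spec <- synthetic_spec(
    n_samples = 9,
    blocks = blocks,
    cross_block = data.frame(a = "AE", b = "AN", rho = -0.8,
                             stringsAsFactors = FALSE),
    meanlog = log(0.01), sdlog = 1,
    group_effects = list(
      list(factor = "do_class", level = "aerobic", blocks = "AE",
           multiplier = 8),
      list(factor = "do_class", level = "anaerobic", blocks = "AN",
           multiplier = 8),
      list(factor = "do_class", level = "aerobic", blocks = "M1",
           multiplier = 3),
      list(factor = "do_class", level = "anaerobic", blocks = "M2",
           multiplier = 3)),
    seed = seed)
  generate_table(spec)
}

#' Write the planted ground truth as JSON
#' @param truth the `truth` element of [generate_table()]'s result.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
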