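#' Bray-Curtis distance matrix between samples
#'
#' d(x, y) = sum|x_i - y_i| / sum(x_i + y_i) over features, in \[0, 1\].
#' A pair of samples that are both all-zero is defined to have distance 0.
#'
#' @param table an [abundance_table()] (distances are between its samples).
#' @return A symmetric sample x sample matrix of class `distance_matrix`
#'   with zero diagonal.
#' @export
bray_curtis <- function(table) {
  stopifnot(inherits(table, "abund_table"))
  v <- t(table$values)
  if (nrow(v) < 2L) stop("at least 2 samples are required")
  if (any(v < 0)) stop("abundances must be non-negative")
  d <- suppressWarnings(as.matrix(vegan::vegdist(v, method = "bray")))
  zero <- rowSums(v) == 0
  if (any(zero)) d[zero, zero] <- 0  # vegdist leaves 0/0 pairs NaN
  diag(d) <- 0
  structure(d, class = c("distance_matrix", class(d)))
}

as_distance_matrix <- function(dm) {
  d <- unclass(as.matrix(dm))
  if (nrow(d) != ncol(d) || !isSymmetric(d, tol = 1e-8))
    stop("distance matrix must be square and symmetric")
  d
}

#' Principal coordinate analysis (classical metric MDS)
#'
#' Gower double-centering of -d^2/2 followed by eigendecomposition.
#' Coordinates are eigenvectors scaled by the square root of their positive
#' eigenvalues; axes with non-positive eigenvalues are reported with zero
#' width (all-zero coordinate columns) so negative eigenvalues remain
#' visible in `eigenvalues` without distorting the configuration.
#'
#' @param dm symmetric distance matrix (a `distance_matrix` or plain matrix).
#' @return A list of class `pcoa_ordination`: `coordinates` (samples x
#'   axes), `eigenvalues` (descending), `proportion_explained` (share of
#'   the positive eigenvalue total; zero for non-positive axes).
#' @export
pcoa <- function(dm) {
  d <- as_distance_matrix(dm)
  n <- nrow(d)
  a <- -0.5 * d^2
  rm <- rowMeans(a)
  b <- a - outer(rm, rm, `+`) + mean(a)  # double-centered Gower matrix
  e <- eigen((b + t(b)) / 2, symmetric = TRUE)
  ev <- e$values
  tol <- max(abs(ev), 0) * 1e-9
  pos <- ev > tol
  coords <- matrix(0, n, n)
  if (any(pos))
    coords[, pos] <- e$vectors[, pos, drop = FALSE] %*%
      diag(sqrt(ev[pos]), sum(pos))
  rownames(coords) <- rownames(d)
  colnames(coords) <- paste0("Axis", seq_len(n))
  pos_total <- sum(ev[pos])
  prop <- if (pos_total > 0) ifelse(pos, ev / pos_total, 0) else rep(0, n)
  structure(list(coordinates = coords, eigenvalues = ev,
                 proportion_explained = prop),
            class = "pcoa_ordination")
}

## All distinct permutations of a multiset (rows of the returned matrix).
multiset_permutations <- function(x) {
  n <- length(x)
  if (n == 1L) return(matrix(x, 1L, 1L))
  ux <- unique(x)
  out <- vector("list", length(ux))
  for (k in seq_along(ux)) {
    rest <- x[-match(ux[k], x)]
    sub <- multiset_permutations(rest)
    out[[k]] <- cbind(ux[k], sub, deparse.level = 0)
  }
  do.call(rbind, out)
}

n_distinct_label_permutations <- function(counts) {
  round(exp(lgamma(sum(counts) + 1) - sum(lgamma(counts + 1))))
}

#' Analysis of similarity (ANOSIM)
#'
#' Rank-based test of group separation on a distance matrix.  The statistic
#' is R = (mean between-group rank - mean within-group rank) / (M / 2) with
#' M = n(n - 1)/2 pairwise distances ranked with average ranks for ties.
#' Significance is assessed by label permutation: when the number of
#' distinct label arrangements is at most `exact_limit` all of them are
#' enumerated (the p-value is then an exact proportion including the
#' observed labeling); otherwise `n_permutations` random relabelings are
#' drawn and p = (#\{R_perm >= R_obs\} + 1) / (n_permutations + 1).
#'
#' @param dm distance matrix.
#' @param grouping group labels, one per sample.
#' @param n_permutations number of random permutations when sampling.
#' @param seed integer seed; required on the sampling path.
#' @param exact_limit enumerate exhaustively when the count of distinct
#'   label arrangements does not exceed this (default 100000).
#' @return A list of class `anosim_result` with `r_statistic`, `p_value`,
#'   `n_permutations` and `method` (`"exact"` or `"sampled"`).
#' @export
anosim <- function(dm, grouping, n_permutations = 10000, seed = NULL,
                   exact_limit = 1e5) {
  d <- as_distance_matrix(dm)
  n <- nrow(d)
  g <- as.factor(grouping)
  if (length(g) != n) stop("`grouping` must have one label per sample")
  counts <- table(g)
  if (nlevels(g) < 2L) stop("at least 2 groups are required")
  if (any(counts < 2L)) stop("every group needs at least 2 samples")
  lower <- lower.tri(d)
  rk <- rank(d[lower])  # average ranks for ties
  idx <- which(lower, arr.ind = TRUE)
  big_m <- n * (n - 1) / 2
  r_stat <- function(lab) {
    within <- lab[idx[, 1L]] == lab[idx[, 2L]]
    (mean(rk[!within]) - mean(rk[within])) / (big_m / 2)
  }
  r_obs <- r_stat(g)
  n_arr <- n_distinct_label_permutations(counts)
  if (n_arr <= exact_limit) {
    perms <- multiset_permutations(as.integer(g))
    r_perm <- apply(perms, 1L, r_stat)
    p <- mean(r_perm >= r_obs - 1e-12)
    np <- nrow(perms)
    method <- "exact"
  } else {
    if (is.null(seed)) stop("`seed` is required for sampled permutations")
    if (n_permutations < 1) stop("`n_permutations` must be at least 1")
    set.seed(seed)
    r_perm <- vapply(seq_len(n_permutations),
                     function(i) r_stat(sample(as.integer(g))), numeric(1))
    p <- (sum(r_perm >= r_obs - 1e-12) + 1) / (n_permutations + 1)
    np <- n_permutations
    method <- "sampled"
  }
  structure(list(r_statistic = r_obs, p_value = p, n_permutations = np,
                 method = method),
            class = "anosim_result")
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%s, %d permutations)\n",
              x$r_statistic, x$p_value, x$method, x$n_permutations))
  invisible(x)
}

#' One-way analysis of variance for a single feature
#'
#' Classical between/within decomposition (equal-variance F test), used to
#' screen features for shifts along an environmental factor.  When the
#' within-group variance is exactly zero the F statistic is unbounded and
#' the result is flagged degenerate with `p_value = NA`.
#'
#' @param values numeric response, one value per sample.
#' @param grouping factor levels, one per sample.
#' @return A list of class `anova_result` with `f_statistic`, `df_between`,
#'   `df_within`, `p_value` and `degenerate`.
#' @export
one_way_anova <- function(values, grouping) {
  g <- as.factor(grouping)
  if (length(values) != length(g)) stop("`values` and `grouping` lengths differ")
  k <- nlevels(g)
  n <- length(values)
  if (k < 2L) stop("at least 2 groups are required")
  if (n <= k) stop("total sample size must exceed the number of groups")
  ssw <- sum(tapply(values, g, function(z) sum((z - mean(z))^2)))
  if (ssw == 0) {
    return(structure(list(f_statistic = Inf, df_between = k - 1L,
                          df_within = n - k, p_value = NA_real_,
                          degenerate = TRUE),
                     class = "anova_result"))
  }
  fit <- stats::oneway.test(values ~ g, var.equal = TRUE)
  structure(list(f_statistic = unname(fit$statistic),
                 df_between = unname(fit$parameter[1L]),
                 df_within = unname(fit$parameter[2L]),
                 p_value = fit$p.value,
                 degenerate = FALSE),
            class = "anova_result")
}

## Shared preprocessing for symmetric Procrustes: match rows, zero-pad
## columns, translate to the centroid, scale to unit sum of squares.
procrustes_prepare <- function(x, y) {
  x <- as.matrix(x)
  y <- as.matrix(y)
  if (!is.null(rownames(x)) && !is.null(rownames(y))) {
    shared <- intersect(rownames(x), rownames(y))
    if (length(shared) < nrow(x) || length(shared) < nrow(y))
      stop("configurations must cover the same sample set")
    y <- y[rownames(x), , drop = FALSE]
  } else if (nrow(x) != nrow(y)) {
    stop("configurations must have the same number of rows")
  }
  if (nrow(x) < 3L) stop("at least 3 samples are required")
  k <- max(ncol(x), ncol(y))
  pad <- function(m) cbind(m, matrix(0, nrow(m), k - ncol(m)))
  x <- pad(x)
  y <- pad(y)
  x <- scale(x, center = TRUE, scale = FALSE)
  y <- scale(y, center = TRUE, scale = FALSE)
  sx <- sqrt(sum(x^2))
  sy <- sqrt(sum(y^2))
  if (sx == 0 || sy == 0)
    stop("a configuration with no spread cannot be superimposed")
  list(x = x / sx, y = y / sy)
}

procrustes_m2 <- function(x, y) {
  1 - sum(svd(crossprod(x, y))$d)^2
}

#' Symmetric Procrustes superimposition of two ordinations
#'
#' Both configurations are translated to their centroids, scaled to unit
#' sum of squares and optimally rotated (reflections permitted) by singular
#' value decomposition.  The badness-of-fit statistic is
#' M^2 = 1 - (sum of singular values)^2, the residual sum of squared
#' distances between matched samples; M^2 = 0 iff the configurations are
#' identical up to translation, scaling and orthogonal transformation.
#'
#' @param x,y sample x axis coordinate matrices; rows are matched by
#'   rowname when both are named, otherwise by position.  Narrower
#'   configurations are zero-padded to equal dimensionality.
#' @return A list of class `procrustes_result` with `m_squared`,
#'   `per_sample_residuals`, `rotation`, `scaling`, `p_value` (NA until
#'   [protest()]), `n_permutations`.
#' @export
procrustes_fit <- function(x, y) {
  pp <- procrustes_prepare(x, y)
  sv <- svd(crossprod(pp$x, pp$y))
  rot <- sv$v %*% t(sv$u)
  scl <- sum(sv$d)
  yrot <- scl * pp$y %*% rot
  res <- sqrt(rowSums((pp$x - yrot)^2))
  names(res) <- rownames(pp$x)
  structure(list(m_squared = max(0, 1 - scl^2),
                 per_sample_residuals = res,
                 rotation = rot, scaling = scl,
                 p_value = NA_real_, n_permutations = 0L),
            class = "procrustes_result")
}

#' @export
print.procrustes_result <- function(x, ...) {
  cat(sprintf("Procrustes: M^2 = %.4g", x$m_squared))
  if (!is.na(x$p_value))
    cat(sprintf(", p = %.4g (%d permutations)", x$p_value, x$n_permutations))
  cat("\n")
  invisible(x)
}

#' Permutation test of Procrustes concordance (protest)
#'
#' Permutes the row order of `y`, refits the symmetric Procrustes
#' superimposition and compares permuted M^2 values with the observed one:
#' p = (#\{M^2_perm <= M^2_obs\} + 1) / (n_permutations + 1).
#'
#' @inheritParams procrustes_fit
#' @param n_permutations number of row permutations (default 10000).
#' @param seed integer seed for the permutation stream.
#' @return A `procrustes_result` with `p_value` and `n_permutations` set.
#' @export
protest <- function(x, y, n_permutations = 10000, seed = NULL) {
  if (n_permutations < 1) stop("`n_permutations` must be at least 1")
  if (is.null(seed)) stop("`seed` is required")
  fit <- procrustes_fit(x, y)
  pp <- procrustes_prepare(x, y)
  n <- nrow(pp$x)
  set.seed(seed)
  m2_perm <- vapply(seq_len(n_permutations), function(i)
    procrustes_m2(pp$x, pp$y[sample(n), , drop = FALSE]), numeric(1))
  fit$p_value <- (sum(m2_perm <= fit$m_squared + 1e-12) + 1) /
    (n_permutations + 1)
  fit$n_permutations <- n_permutations
  fit
}
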