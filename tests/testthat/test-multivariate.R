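test_that("Bray-Curtis matches hand values and the degenerate conventions", {
  m <- toy_matrix(c(1, 3, 3, 1) / 4, c("f1", "f2"), c("x", "y"))
  d <- bray_curtis(toy_table(m))
  expect_equal(d["x", "y"], 0.5)  # (2+2)/(4+4)

  m2 <- toy_matrix(c(0.5, 0.5, 0, 0,   # s1
                     0, 0, 0.7, 0.3,   # s2: support disjoint from s1
                     0, 0, 0, 0,       # s3: empty
                     0, 0, 0, 0,       # s4: empty
                     0.5, 0.5, 0, 0),  # s5: identical to s1
                   c("f1", "f2", "f3", "f4"),
                   c("s1", "s2", "s3", "s4", "s5"))
  d2 <- bray_curtis(toy_table(m2))
  expect_equal(d2["s1", "s5"], 0)          # identical columns
  expect_equal(d2["s1", "s2"], 1)          # disjoint support
  expect_equal(d2["s1", "s3"], 1)          # something vs nothing
  expect_equal(d2["s3", "s4"], 0)          # both all-zero -> defined as 0
})

test_that("Bray-Curtis is a symmetric semimetric in [0,1] and agrees with vegan", {
  set.seed(11)
  m <- matrix(stats::rexp(8 * 6), 8, 6,
              dimnames = list(sprintf("f%d", 1:8), sprintf("s%d", 1:6)))
  m <- sweep(m, 2, colSums(m), `/`)
  d <- bray_curtis(toy_table(m))
  expect_equal(unclass(d), t(unclass(d)), ignore_attr = TRUE)
  expect_true(all(d >= 0 & d <= 1))
  expect_equal(unname(diag(d)), rep(0, 6))
  ref <- as.matrix(vegan::vegdist(t(m), method = "bray"))
  expect_equal(unclass(d), ref, ignore_attr = TRUE, tolerance = 1e-12)
})

test_that("PCoA reproduces Euclidean distances and axis counts exactly", {
  # collinear points at 0, 1, 3 -> one positive eigenvalue
  pts1 <- matrix(c(0, 1, 3), ncol = 1, dimnames = list(c("a", "b", "c"), NULL))
  ord1 <- pcoa(euclid_dm(pts1))
  tol <- max(abs(ord1$eigenvalues)) * 1e-8
  expect_equal(sum(ord1$eigenvalues > tol), 1)
  expect_equal(as.matrix(dist(ord1$coordinates)), euclid_dm(pts1),
               tolerance = 1e-8, ignore_attr = TRUE)

  # planar 4-point configuration -> two positive eigenvalues
  pts2 <- matrix(c(0, 0, 1, 0, 1, 2, -1, 1), 4, 2, byrow = TRUE,
                 dimnames = list(sprintf("p%d", 1:4), NULL))
  ord2 <- pcoa(euclid_dm(pts2))
  tol2 <- max(abs(ord2$eigenvalues)) * 1e-6
  expect_equal(sum(ord2$eigenvalues > tol2), 2)
  expect_equal(as.matrix(dist(ord2$coordinates)), euclid_dm(pts2),
               tolerance = 1e-8, ignore_attr = TRUE)

  # all-zero distances -> all-zero coordinates
  z <- matrix(0, 3, 3, dimnames = list(letters[1:3], letters[1:3]))
  expect_true(all(pcoa(z)$coordinates == 0))
  expect_error(pcoa(matrix(c(0, 1, 2, 0), 2)), "symmetric")
})

test_that("PCoA agrees with classical scaling (cmdscale) on random data", {
  set.seed(4)
  m <- matrix(stats::rexp(10 * 7), 10, 7,
              dimnames = list(sprintf("f%d", 1:10), sprintf("s%d", 1:7)))
  m <- sweep(m, 2, colSums(m), `/`)
  d <- bray_curtis(toy_table(m))
  ord <- pcoa(d)
  ref <- stats::cmdscale(stats::as.dist(unclass(d)), k = 2, eig = TRUE)
  expect_equal(ord$eigenvalues[1:2], ref$eig[1:2], tolerance = 1e-8)
  expect_equal(abs(ord$coordinates[, 1:2]), abs(ref$points),
               tolerance = 1e-6, ignore_attr = TRUE)
  expect_true(sum(ord$proportion_explained) <= 1 + 1e-12)
})

test_that("ANOSIM gives R = 1 for perfect separation and a valid p floor", {
  # two tight groups far apart: every between distance beats every within
  pts <- matrix(c(0, 0.1, 0.2, 10, 10.1, 10.2), ncol = 1,
                dimnames = list(sprintf("s%d", 1:6), NULL))
  res <- anosim(euclid_dm(pts), rep(c("g1", "g2"), each = 3))
  expect_equal(res$r_statistic, 1)
  expect_identical(res$method, "exact")
  expect_gte(res$p_value, 1 / (res$n_permutations + 1))
})

test_that("exact ANOSIM enumeration matches sampled estimates within binomial error", {
  set.seed(21)
  pts <- matrix(stats::rnorm(8), ncol = 2,
                dimnames = list(sprintf("s%d", 1:4), NULL))
  dm <- euclid_dm(pts)
  g <- c("a", "a", "b", "b")
  ex <- anosim(dm, g)                      # 6 distinct arrangements
  expect_identical(ex$method, "exact")
  sm <- anosim(dm, g, n_permutations = 10000, seed = 5, exact_limit = 0)
  expect_identical(sm$method, "sampled")
  se <- sqrt(ex$p_value * (1 - ex$p_value) / 10000)
  expect_lt(abs(sm$p_value - ex$p_value), 3 * se + 2e-4)
})

test_that("ANOSIM p is roughly uniform under exchangeable labels", {
  set.seed(31)
  ps <- replicate(120, {
    pts <- matrix(stats::rnorm(12), ncol = 2,
                  dimnames = list(sprintf("s%d", 1:6), NULL))
    anosim(euclid_dm(pts), rep(c("a", "b"), each = 3))$p_value
  })
  expect_gt(mean(ps), 0.35)
  expect_lt(mean(ps), 0.75)
})

test_that("ANOSIM validates its grouping", {
  dm <- euclid_dm(matrix(1:4, ncol = 1,
                         dimnames = list(sprintf("s%d", 1:4), NULL)))
  expect_error(anosim(dm, c("a", "a", "a", "b")), "at least 2 samples")
  expect_error(anosim(dm, rep("a", 4)), "2 groups")
})

test_that("one-way ANOVA equals the squared two-sample t statistic", {
  set.seed(8)
  x <- stats::rnorm(14)
  g <- rep(c("u", "v"), each = 7)
  res <- one_way_anova(x, g)
  tt <- stats::t.test(x ~ g, var.equal = TRUE)
  expect_equal(res$f_statistic, unname(tt$statistic)^2)
  expect_equal(res$p_value, tt$p.value)
  expect_equal(res$df_between, 1)
  expect_equal(res$df_within, 12)
})

test_that("zero within-group variance is flagged degenerate", {
  res <- one_way_anova(c(1, 1, 1, 2, 2, 2), rep(c("a", "b"), each = 3))
  expect_true(res$degenerate)
  expect_identical(res$f_statistic, Inf)
  expect_true(is.na(res$p_value))
})

test_that("ANOVA p is roughly uniform under a common distribution", {
  set.seed(9)
  ps <- replicate(300, one_way_anova(stats::rnorm(12),
                                     rep(c("a", "b", "c"), 4))$p_value)
  expect_gt(mean(ps), 0.4)
  expect_lt(mean(ps), 0.6)
})

test_that("Procrustes M^2 vanishes for superimposable configurations", {
  set.seed(14)
  x <- matrix(stats::rnorm(10), 5, 2, dimnames = list(sprintf("s%d", 1:5), NULL))
  th <- 0.7
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  y <- 2.5 * x %*% rot + matrix(c(3, -1), 5, 2, byrow = TRUE)
  rownames(y) <- rownames(x)
  expect_equal(procrustes_fit(x, y)$m_squared, 0, tolerance = 1e-12)

  y_ref <- x %*% diag(c(-1, 1))   # reflection is permitted
  rownames(y_ref) <- rownames(x)
  expect_equal(procrustes_fit(x, y_ref)$m_squared, 0, tolerance = 1e-12)
  expect_error(procrustes_fit(x[1:2, ], y[1:2, ]), "at least 3")
})

test_that("Procrustes matches the closed form and vegan's symmetric fit", {
  x <- matrix(c(0, 0, 1, 0, 0, 2), 3, 2, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), NULL))
  y <- matrix(c(0.1, 0.2, 1.3, -0.1, -0.4, 1.9), 3, 2, byrow = TRUE,
              dimnames = list(c("s1", "s2", "s3"), NULL))
  # independent evaluation of 1 - (sum of singular values)^2
  cx <- scale(x, scale = FALSE); cx <- cx / sqrt(sum(cx^2))
  cy <- scale(y, scale = FALSE); cy <- cy / sqrt(sum(cy^2))
  expected <- 1 - sum(svd(t(cx) %*% cy)$d)^2
  fit <- procrustes_fit(x, y)
  expect_equal(fit$m_squared, expected, tolerance = 1e-12)
  ref <- vegan::procrustes(x, y, symmetric = TRUE)
  expect_equal(fit$m_squared, ref$ss, tolerance = 1e-10)
  # residual sum of squares equals M^2
  expect_equal(sum(fit$per_sample_residuals^2), fit$m_squared,
               tolerance = 1e-10)
})

test_that("protest p-values behave under identity, null and rotation", {
  set.seed(17)
  x <- matrix(stats::rnorm(12), 6, 2, dimnames = list(sprintf("s%d", 1:6), NULL))
  res <- protest(x, x, n_permutations = 999, seed = 3)
  expect_lt(res$p_value, 0.02)  # only identity-equivalent permutations tie

  y <- matrix(stats::rnorm(12), 6, 2, dimnames = list(sprintf("s%d", 1:6), NULL))
  null_p <- protest(x, y, n_permutations = 999, seed = 3)$p_value
  expect_gte(null_p, 1 / 1000)

  th <- 1.1
  rot <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2)
  xr <- x %*% rot; yr <- y %*% rot
  rownames(xr) <- rownames(yr) <- rownames(x)
  expect_equal(protest(xr, yr, n_permutations = 499, seed = 9)$p_value,
               protest(x, y, n_permutations = 499, seed = 9)$p_value)
  expect_error(protest(x, y, n_permutations = 0, seed = 1), "at least 1")
})

test_that("protest agrees with vegan::protest on the same configurations", {
  set.seed(23)
  x <- matrix(stats::rnorm(14), 7, 2, dimnames = list(sprintf("s%d", 1:7), NULL))
  y <- x + 0.35 * matrix(stats::rnorm(14), 7, 2)
  rownames(y) <- rownames(x)
  mine <- protest(x, y, n_permutations = 999, seed = 2)
  ref <- vegan::protest(x, y, permutations = 999)
  expect_equal(mine$m_squared, ref$ss, tolerance = 1e-10)
  # both tests should call the association at the same significance
  expect_lt(mine$p_value, 0.05)
  expect_lt(ref$signif, 0.05)
})
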