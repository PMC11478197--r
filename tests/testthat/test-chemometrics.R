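test_that("preprocess implements the standard scalings and inverts", {
  x <- cbind(a = c(1, 2, 3), b = c(10, 30, 20))
  uv <- preprocess(x, "uv")
  expect_equal(uv$values[, "a"], c(-1, 0, 1), ignore_attr = TRUE)
  expect_equal(colMeans(uv$values), c(a = 0, b = 0), tolerance = 1e-10)
  expect_equal(apply(uv$values, 2, sd), c(a = 1, b = 1), tolerance = 1e-10)
  expect_identical(preprocess(x, "none")$values, x)
  # an already-standardized matrix is unchanged by uv
  z <- scale(matrix(rnorm(40), 10))
  attr(z, "scaled:center") <- attr(z, "scaled:scale") <- NULL
  expect_equal(preprocess(z, "uv")$values, z, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(unscale(uv), x, ignore_attr = TRUE)
  bad <- cbind(ok = c(1, 2, 3), flat = c(5, 5, 5))
  expect_error(preprocess(bad, "uv"), "flat")
  expect_error(preprocess(x[1, , drop = FALSE]), "2 rows")
})

test_that("PCA explains rank-2 data fully and duplicates behave", {
  set.seed(3)
  basis <- matrix(rnorm(2 * 8), 2, 8)
  x <- matrix(rnorm(12 * 2), 12, 2) %*% basis
  p <- pca_fit(preprocess(x, "center"), k = 2)
  expect_equal(p$r2cum[2], 1, tolerance = 1e-10)
  expect_true(all(diff(p$eigenfractions) <= 1e-12))
  # duplicating every row duplicates scores, leaves loadings unchanged
  p2 <- pca_fit(preprocess(rbind(x, x), "center"), k = 2)
  al <- sign(colSums(p$loadings * p2$loadings))  # sign indeterminacy
  expect_equal(sweep(p2$loadings, 2, al, `*`), p$loadings,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_error(pca_fit(preprocess(x, "center"), k = 12), "k too large")
})

test_that("PCA reconstruction with all components is exact", {
  set.seed(4)
  x <- matrix(rnorm(15 * 6), 15, 6)
  sm <- preprocess(x, "uv")
  k <- min(nrow(x) - 1, ncol(x))
  p <- pca_fit(sm, k = k)
  expect_equal(p$scores %*% t(p$loadings), sm$values, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(abs(crossprod(p$loadings) - diag(k)) < 1e-8))
})

test_that("PCA eigenfractions of isotropic noise are near-uniform", {
  set.seed(5)
  x <- matrix(rnorm(500 * 8), 500, 8)
  p <- pca_fit(preprocess(x, "uv"), k = 8, nfold = 2)
  expect_true(all(p$eigenfractions > 0.08 & p$eigenfractions < 0.18))
})

test_that("HCA separates distant clouds and selects k by silhouette", {
  set.seed(6)
  x <- rbind(matrix(rnorm(40, 0), 10), matrix(rnorm(40, 8), 10))
  h <- hca_fit(preprocess(x, "center"), k = 2)
  expect_equal(adjusted_rand(h$labels, rep(1:2, each = 10)), 1)
  hs <- hca_fit(preprocess(x, "center"))  # silhouette-selected
  expect_identical(hs$k, 2L)
  # a panel of identical rows yields a zero-height tree
  same <- matrix(1:5, 6, 5, byrow = TRUE)
  h0 <- hca_fit(preprocess(same, "none"))
  expect_true(all(h0$hclust$height == 0))
  expect_error(hca_fit(preprocess(x, "center"), k = 99), "exceed")
})

test_that("hclust dendrograms serialize to parseable Newick text", {
  x <- matrix(rnorm(20), 5, 4,
              dimnames = list(paste0("S", 1:5), NULL))
  h <- hca_fit(preprocess(x, "center"), k = 2)
  nwk <- hclust_to_newick(h$hclust)
  expect_match(nwk, "^\\(.*\\);$")
  for (b in rownames(x)) expect_match(nwk, b, fixed = TRUE)
})

test_that("OPLS-DA fits separable classes and reduces to PLS", {
  set.seed(8)
  n <- 20
  y <- rep(c("a", "b"), each = n / 2)
  x <- matrix(rnorm(n * 10, sd = 0.02), n, 10)
  x[, 1] <- x[, 1] + ifelse(y == "a", -2, 2)
  sm <- preprocess(x, "center")
  m <- oplsda_fit(sm, y)
  expect_gt(m$r2y, 0.99)
  expect_gt(m$q2, 0.9)
  expect_lte(m$q2, m$r2y)
  expect_true(m$r2x >= 0 && m$r2x <= 1)
  # n_orthogonal = 0 equals single-component PLS (oracle: NIPALS closed
  # form for one component)
  m0 <- oplsda_fit(sm, y, n_orthogonal = 0)
  yc <- ifelse(y == "a", -1, 1); yc <- yc - mean(yc)
  w <- drop(crossprod(sm$values, yc)); w <- w / sqrt(sum(w^2))
  expect_equal(m0$t, drop(sm$values %*% w), tolerance = 1e-8)
  expect_error(oplsda_fit(sm, rep("a", n)), "2 non-empty classes")
})

test_that("predictive scores ignore the fitted orthogonal variation", {
  set.seed(9)
  x <- matrix(rnorm(18 * 12), 18, 12)
  y <- rep(c(0, 1), 9)
  sm <- preprocess(x, "uv")
  m <- oplsda_fit(sm, y, n_orthogonal = 1)
  filtered <- sm$values - tcrossprod(m$To, m$Po)
  m2 <- oplsda_fit(preprocess(filtered, "none"), y, n_orthogonal = 0)
  expect_equal(m2$t, m$t, tolerance = 1e-8)
})

test_that("null-model Q2 is non-positive in median over seeds", {
  q2 <- vapply(1:9, function(s) {
    set.seed(100 + s)
    x <- matrix(rnorm(18 * 30), 18, 30)
    y <- sample(rep(c("a", "b"), 9))
    oplsda_fit(preprocess(x, "uv"), y)$q2
  }, numeric(1))
  expect_lte(stats::median(q2), 0)
})

test_that("VIP satisfies its algebraic identities", {
  set.seed(10)
  for (i in 1:5) {
    x <- matrix(rnorm(16 * (5 + i)), 16)
    y <- rep(c("a", "b"), 8)
    v <- vip(oplsda_fit(preprocess(x, "uv"), y))
    expect_equal(mean(v^2), 1, tolerance = 1e-8)
  }
  # one informative variable attains the maximum VIP
  x <- matrix(rnorm(20 * 8, sd = 0.3), 20, 8)
  y <- rep(c("a", "b"), each = 10)
  x[, 4] <- ifelse(y == "a", -1, 1) + rnorm(20, sd = 0.05)
  v <- vip(oplsda_fit(preprocess(x, "uv"), y))
  expect_equal(unname(which.max(v)), 4L)
  expect_true("4" %in% attr(v, "flagged"))
  # all variables identical: all VIP exactly 1
  x1 <- matrix(rnorm(20, sd = 0.3) + ifelse(y == "a", -1, 1), 20, 6)
  v1 <- vip(oplsda_fit(preprocess(x1, "uv"), y))
  expect_equal(unname(v1), rep(1, 6), tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("permutation testing flags null data and keeps the identity row", {
  set.seed(11)
  x <- matrix(rnorm(18 * 10), 18, 10)
  y <- rep(c("a", "b"), 9)
  intercepts <- vapply(1:5, function(s)
    permutation_test(preprocess(x, "uv"), y, n_perm = 30,
                     seed = s)$q2_intercept, numeric(1))
  expect_gte(mean(intercepts <= 0), 0.9)
  pr <- permutation_test(preprocess(x, "uv"), y, n_perm = 25, seed = 2)
  orig <- pr$record[pr$record$perm_id == 0, ]
  expect_equal(orig$corr, 1)
  expect_equal(orig$q2, oplsda_fit(preprocess(x, "uv"), y)$q2)
  expect_error(permutation_test(preprocess(x, "uv"), y, n_perm = 5),
               "n_perm")
})
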