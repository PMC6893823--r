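# Standardization, PCA and class-separation statistics.

test_that("z-scoring uses the population-sd convention", {
  z <- standardizeDescriptors(cbind(a = c(1, 2, 3)))
  expect_equal(as.numeric(z), c(-1.2247449, 0, 1.2247449),
               tolerance = 1e-6)
  expect_error(standardizeDescriptors(cbind(a = 1)), "2 rows")

  m <- cbind(a = c(1, 5, 9, 2), b = rep(7, 4))
  expect_warning(z2 <- standardizeDescriptors(m), "constant")
  expect_identical(colnames(z2), "a")
  expect_identical(attr(z2, "dropped"), "b")
  expect_lt(abs(mean(z2[, "a"])), 1e-12)
})

test_that("PCA recovers closed-form eigenstructure", {
  # perfectly correlated columns: one component explains everything
  x <- cbind(a = c(-1, 0, 1, 2), b = c(-1, 0, 1, 2))
  pc <- pcaDescriptors(x)
  expect_equal(pc@explainedVariance[1], 1)

  # sample covariance exactly [[2,1],[1,2]] -> eigenvalues 3 and 1
  A <- matrix(c(1, 1, -1, -1, 1, -1, -1, 1), ncol = 2)
  S <- matrix(c(2, 1, 1, 2), 2)
  X <- A %*% chol(S)  # sample covariance proportional to S
  ref <- eigen2x2(2, 1, 2)
  pc2 <- pcaDescriptors(X)
  expect_equal(pc2@explainedVariance, ref / sum(ref), tolerance = 1e-12)

  # orthonormal loadings, deterministic sign
  L <- pc2@loadings
  expect_equal(crossprod(L), diag(2), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(apply(L, 2, function(col) col[which.max(abs(col))] > 0)))
})

test_that("scores reconstruct the data when all components are kept", {
  set.seed(42)
  x <- matrix(rnorm(60), 12, 5)
  pc <- pcaDescriptors(x)
  rec <- pc@scores %*% t(pc@loadings)
  centered <- sweep(x, 2, colMeans(x))
  expect_equal(rec, centered, tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("row permutation permutes scores identically", {
  set.seed(7)
  x <- matrix(rnorm(80), 16, 5)
  perm <- sample(nrow(x))
  pc <- pcaDescriptors(x)
  pcp <- pcaDescriptors(x[perm, ])
  expect_equal(pcp@scores, pc@scores[perm, ], tolerance = 1e-10,
               ignore_attr = TRUE)
})

test_that("requesting more components than the rank truncates", {
  x <- cbind(a = c(-1, 0, 1), b = c(-2, 0, 2))  # rank 1
  expect_warning(pc <- pcaDescriptors(x, nComponents = 2), "rank")
  expect_identical(ncol(pc@scores), 1L)
})

test_that("silhouette separates distant blobs and matches the oracle", {
  set.seed(11)
  blob1 <- matrix(rnorm(40, 0, 0.5), ncol = 2)
  blob2 <- matrix(rnorm(40, 10, 0.5), ncol = 2)
  pts <- rbind(blob1, blob2)
  cls <- factor(rep(c("a", "b"), each = 20))
  sep <- classSeparation(pts, cls)
  expect_gt(sep$overall, 0.5)
  expect_equal(sep$overall, bruteSilhouette(pts, as.character(cls)),
               tolerance = 1e-12)
})

test_that("shuffled labels give near-zero silhouette", {
  set.seed(13)
  pts <- matrix(rnorm(120), ncol = 2)
  cls <- factor(rep(c("a", "b", "c"), each = 20))
  vals <- replicate(100, {
    classSeparation(pts, sample(cls))$overall
  })
  expect_lt(max(abs(vals)), 0.15)
})

test_that("identical duplicated classes give non-positive silhouette", {
  set.seed(5)
  pts <- matrix(rnorm(30), ncol = 2)
  both <- rbind(pts, pts)
  cls <- factor(rep(c("a", "b"), each = nrow(pts)))
  expect_lte(classSeparation(both, cls)$overall, 0)
})

test_that("singleton classes are excluded with a warning", {
  pts <- matrix(rnorm(14), ncol = 2)
  cls <- factor(c(rep("a", 3), rep("b", 3), "single"))
  expect_warning(sep <- classSeparation(pts, cls), "singleton")
  expect_identical(sep$n_used, 6L)
  expect_error(
    suppressWarnings(classSeparation(pts, factor(c(rep("a", 6),
                                                   "single")))),
    "two classes")
})

test_that("logBB window census counts strictly-inside values", {
  v <- data.frame(id = letters[1:4],
                  logbb = c(-3.5, -3.0, -2.9, 1.0))
  cen <- logbbWindowCensus(v, classes = c("g", "g", "u", "u"))
  expect_equal(cen$fraction_inside, 0.5)
  expect_identical(cen$n_total, 4L)
  expect_identical(sort(cen$outside$id), c("a", "b"))  # boundary outside
  all_in <- logbbWindowCensus(data.frame(id = "x", logbb = 0))
  expect_equal(all_in$fraction_inside, 1.0)
})
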