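test_that("PCA eigenvalues match hand-computed cases", {
  # duplicated column: rank 1, all variance on the first component
  c1 <- c(0, 1, 2, 3)
  m <- fitPCA(cbind(c1, c1))
  expect_equal(m@relativeEigenvalues, c(1, 0), tolerance = 1e-12)

  # unit square: covariance is (1/3) I, equal eigenvalues
  Y <- rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1))
  m2 <- fitPCA(Y)
  expect_equal(m2@eigenvalues, c(1 / 3, 1 / 3), tolerance = 1e-12)
  expect_equal(m2@relativeEigenvalues, c(0.5, 0.5), tolerance = 1e-12)

  # trace preservation on a random matrix
  Yr <- randomY(40, 7, seed = 2)
  m3 <- fitPCA(Yr)
  expect_equal(sum(m3@eigenvalues), sum(apply(Yr, 2, var)),
               tolerance = 1e-9)

  expect_error(fitPCA(matrix(1, 1, 3)), "at least 2")
  expect_warning(m0 <- fitPCA(matrix(2, 5, 3)), "rank-0")
  expect_equal(sum(m0@eigenvalues), 0)
})

test_that("type-1 scores preserve pairwise distances and center at zero", {
  Y <- randomY(10, 6, seed = 3)
  m <- fitPCA(Y)
  S <- featureValues(transformPCA(m, Y))
  Yc <- scale(Y, scale = FALSE)
  expect_lt(max(abs(dist(S) - dist(Yc))), 1e-9)
  expect_lt(max(abs(colMeans(S))), 1e-12)

  # reconstruction at full rank
  back <- S %*% t(m@loadings) + rep(1, 10) %*% t(m@center)
  expect_lt(max(abs(back - Y)), 1e-9)

  # rotation invariance of the total sum of squares
  expect_equal(spectralGamma(S)$ssGamma, spectralGamma(Y)$ssGamma,
               tolerance = 1e-9)

  expect_error(transformPCA(m, Y, nComponents = 9), "1\\.\\.6")
  expect_error(transformPCA(m, Y, nComponents = 2, varianceTarget = 0.9),
               "mutually exclusive")
})

test_that("loading signs are deterministic and do not affect diversity", {
  Y <- randomY(30, 5, seed = 8)
  m1 <- fitPCA(Y)
  set.seed(21)
  m2 <- fitPCA(Y[sample(30), ])    # row order must not flip signs
  expect_equal(m1@loadings, m2@loadings, tolerance = 1e-9,
               ignore_attr = TRUE)
  maxel <- apply(m1@loadings, 2, function(v) v[which.max(abs(v))])
  expect_true(all(maxel > 0))
})

test_that("variance-target selection picks the smallest sufficient rank", {
  Y <- cbind(randomY(50, 1, seed = 5) * 10, randomY(50, 2, seed = 6))
  m <- fitPCA(Y)
  k <- nFeatures(transformPCA(m, Y, varianceTarget = 0.9))
  cum <- cumsum(m@relativeEigenvalues)
  expect_true(cum[k] >= 0.9 && (k == 1 || cum[k - 1] < 0.9))
  expect_equal(nFeatures(transformPCA(m, Y, varianceTarget = 1)), 3)
})

test_that("gamma feature contributions on full-rank scores equal relative eigenvalues", {
  Y <- randomY(60, 8, seed = 13)
  m <- fitPCA(Y)
  S <- transformPCA(m, Y)
  g <- spectralGamma(S)
  expect_equal(g$fcsdGamma, m@relativeEigenvalues, tolerance = 1e-9,
               ignore_attr = TRUE)
})
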