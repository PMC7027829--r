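test_that("with equal counts every repeat equals the plain partition", {
  Y <- randomY(30, 3, seed = 2)
  grid <- equalGrid(5, 6)
  plain <- partitionDiversity(Y, grid)
  rar <- rarefiedPartition(Y, grid, repeats = 4, seed = 99)
  expect_equal(rar@mMin, 6L)
  agg <- rar@aggregate
  expect_equal(ssGamma(agg), ssGamma(plain), tolerance = 1e-12)
  expect_equal(ssBeta(agg), ssBeta(plain), tolerance = 1e-12)
  expect_equal(lcsdGamma(agg), lcsdGamma(plain), tolerance = 1e-12)
  expect_equal(fcsdAlpha(agg), fcsdAlpha(plain), tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("unequal counts rarefy to the minimum and stay reproducible", {
  set.seed(7)
  k <- rep(1:3, times = c(16, 14, 16))
  Y <- matrix(rnorm(length(k) * 2), ncol = 2)
  grid <- communityGrid(k)
  r1 <- rarefiedPartition(Y, grid, repeats = 5, seed = 42)
  expect_equal(r1@mMin, 14L)
  expect_true(all(vapply(r1@perRepeat, function(p) p@m, integer(1)) == 14L))
  expect_true(all(vapply(r1@perRepeat, function(p) p@n, integer(1)) == 42L))

  # bit-identical rerun under the same master seed
  r2 <- rarefiedPartition(Y, grid, repeats = 5, seed = 42)
  expect_identical(ssGamma(r1@aggregate), ssGamma(r2@aggregate))
  expect_identical(lcsdGamma(r1@aggregate), lcsdGamma(r2@aggregate))

  # different seed gives different draws
  r3 <- rarefiedPartition(Y, grid, repeats = 5, seed = 43)
  expect_false(identical(ssGamma(r1@aggregate), ssGamma(r3@aggregate)))
})

test_that("mean aggregation preserves additivity; median is available", {
  set.seed(8)
  k <- rep(1:4, times = c(10, 8, 9, 12))
  Y <- matrix(rnorm(length(k) * 3), ncol = 3)
  grid <- communityGrid(k)
  r <- rarefiedPartition(Y, grid, repeats = 6, seed = 1)
  agg <- r@aggregate
  expect_equal(ssGamma(agg), ssBeta(agg) + ssAlpha(agg), tolerance = 1e-9)

  rmed <- rarefiedPartition(Y, grid, repeats = 6, seed = 1,
                            aggregation = "median")
  ssg <- vapply(rmed@perRepeat, ssGamma, numeric(1))
  expect_equal(ssGamma(rmed@aggregate), median(ssg))
})

test_that("per-pixel contributions aggregate only over drawn repeats", {
  set.seed(9)
  k <- rep(1:2, times = c(4, 2))
  Y <- matrix(rnorm(12), ncol = 2)
  grid <- communityGrid(k)
  r <- rarefiedPartition(Y, grid, repeats = 10, seed = 5)
  lg <- lcsdGamma(r@aggregate)
  # community 2 pixels are drawn every repeat; community 1 pixels only when
  # sampled, but with 10 repeats of 2-from-4 every pixel appears eventually
  expect_equal(length(lg), 6)
  expect_true(all(is.finite(lg)))
})

test_that("undersized communities error and the floor can drop them", {
  k <- rep(1:3, times = c(6, 1, 6))
  Y <- matrix(rnorm(13 * 2), ncol = 2)
  grid <- communityGrid(k)
  expect_error(rarefiedPartition(Y, grid, repeats = 2, seed = 1),
               "fewer than 2 valid pixels: 2")
  # floor at half the largest count drops the singleton community
  r <- rarefiedPartition(Y, grid, repeats = 2, seed = 1, minFraction = 0.5)
  expect_equal(r@aggregate@q, 2L)
  expect_equal(names(r@aggregate@ssAlphaK), c("1", "3"))
})
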