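test_that("square tiling produces the expected community layouts", {
  coords25 <- as.matrix(expand.grid(row = 0:24, col = 0:24))
  g <- makeCommunityGrid(coords25, 5, c(25, 25))
  expect_equal(nCommunities(g), 25)
  expect_true(all(communityCounts(g) == 25))

  # a 280 x 1000 scene tiled into 40 px plots
  gBig <- makeCommunityGrid(cbind(0L, 0L), 40, c(280, 1000))
  expect_equal(nCommunities(gBig), 7 * 25)

  # incomplete edge strips are discarded
  coords10 <- as.matrix(expand.grid(row = 0:9, col = 0:9))
  g10 <- makeCommunityGrid(coords10, 3, c(10, 10))
  expect_equal(nCommunities(g10), 9)
  expect_equal(sum(is.na(communityAssignment(g10))), 100 - 81)

  expect_error(makeCommunityGrid(cbind(0L, 0L), 5, c(4, 4)),
               "no complete")
})

test_that("tiling is row-major from the top-left origin", {
  coords <- as.matrix(expand.grid(col = 0:5, row = 0:3))[, 2:1]
  g <- makeCommunityGrid(coords, 2, c(4, 6))
  a <- communityAssignment(g)
  # pixel (0,0) -> community 1; (0,2) -> 2; (2,0) -> 4 (second tile row)
  expect_equal(a[coords[, 1] == 0 & coords[, 2] == 0], 1)
  expect_equal(a[coords[, 1] == 0 & coords[, 2] == 2], 2)
  expect_equal(a[coords[, 1] == 2 & coords[, 2] == 0], 4)
})

test_that("gamma partition matches hand arithmetic", {
  g <- spectralGamma(matrix(c(0, 2, 0, 2), ncol = 1))
  expect_equal(g$ssGamma, 4)
  expect_equal(g$sdGamma, 4 / 3)
  expect_equal(g$lcsdGamma, rep(0.25, 4))
  expect_equal(g$fcsdGamma, 1, ignore_attr = TRUE)

  # degenerate: identical rows
  g0 <- spectralGamma(matrix(1, 4, 2))
  expect_equal(g0$ssGamma, 0)
  expect_true(all(is.na(g0$lcsdGamma)))

  expect_error(spectralGamma(matrix(1, 1, 2)), "at least 2")
})

test_that("beta and alpha partitions match hand arithmetic", {
  grid <- equalGrid(2, 2)
  # all among-community variation
  b <- spectralBeta(matrix(c(0, 0, 2, 2), ncol = 1), grid)
  expect_equal(b$ssBeta, 4)
  expect_equal(b$lcsdBeta, c(0.5, 0.5), ignore_attr = TRUE)
  a <- spectralAlpha(matrix(c(0, 0, 2, 2), ncol = 1), grid)
  expect_equal(a$ssAlpha, 0)
  expect_true(all(is.na(a$fcsdAlpha)))

  # all within-community variation
  b2 <- spectralBeta(matrix(c(0, 2, 0, 2), ncol = 1), grid)
  expect_equal(b2$ssBeta, 0)
  expect_true(all(is.na(b2$lcsdBeta)))
  a2 <- spectralAlpha(matrix(c(0, 2, 0, 2), ncol = 1), grid)
  expect_equal(a2$ssAlpha, 4)
  expect_equal(a2$sdAlphaK, c(2, 2), ignore_attr = TRUE)

  # m-weighted centroids average back to the global mean
  Y <- randomY(24, 3, seed = 17)
  b3 <- spectralBeta(Y, equalGrid(4, 6))
  expect_equal(colMeans(b3$centroids), colMeans(Y), tolerance = 1e-12)

  expect_error(spectralBeta(matrix(1:6, ncol = 1), communityGrid(c(1, 1, 1, 1, 2, 2))),
               "rarefiedPartition")
  expect_error(spectralAlpha(matrix(1:2, ncol = 1), equalGrid(2, 1)),
               "single-pixel")
})

test_that("the additive partition agrees with a per-feature ANOVA oracle", {
  Y <- randomY(60, 4, seed = 23)
  grid <- equalGrid(6, 10)
  p <- partitionDiversity(Y, grid)
  oracle <- ssAnovaOracle(Y, communityAssignment(grid))
  expect_equal(ssBeta(p), oracle$between, tolerance = 1e-9)
  expect_equal(ssAlpha(p), oracle$within, tolerance = 1e-9)
  expect_equal(ssGamma(p), ssBeta(p) + ssAlpha(p), tolerance = 1e-9)
})

test_that("contribution indices are normalized and respond to scaling as squares", {
  Y <- randomY(36, 5, seed = 31)
  grid <- equalGrid(6, 6)
  p <- partitionDiversity(Y, grid)
  expect_equal(sum(lcsdGamma(p)), 1, tolerance = 1e-9)
  expect_equal(sum(lcsdBeta(p)), 1, tolerance = 1e-9)
  expect_equal(sum(fcsdGamma(p)), 1, tolerance = 1e-9)
  expect_equal(sum(fcsdBeta(p)), 1, tolerance = 1e-9)
  expect_equal(rowSums(fcsdAlpha(p)), rep(1, 6), tolerance = 1e-9,
               ignore_attr = TRUE)

  ps <- partitionDiversity(3 * Y, grid)
  expect_equal(ssGamma(ps), 9 * ssGamma(p), tolerance = 1e-9)
  expect_equal(sdBeta(ps), 9 * sdBeta(p), tolerance = 1e-9)
  expect_equal(lcsdGamma(ps), lcsdGamma(p), tolerance = 1e-9)
  expect_equal(fcsdBeta(ps), fcsdBeta(p), tolerance = 1e-9)
})

test_that("permuting pixel rows preserves gamma but changes beta", {
  Y <- randomY(40, 3, seed = 41)
  grid <- equalGrid(8, 5)
  p1 <- partitionDiversity(Y, grid)
  set.seed(42)
  p2 <- partitionDiversity(Y[sample(40), ], grid)
  expect_equal(ssGamma(p2), ssGamma(p1), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(ssBeta(p2), ssBeta(p1))))
})

test_that("region merging follows the pooled-pixel rule", {
  expect_equal(mergeRegions(ss = 4, n = 4)$sdGamma, 4 / 3)
  joint <- mergeRegions(ss = c(4, 4), n = c(4, 4))
  expect_equal(joint$ssGamma, 8)
  expect_equal(joint$sdGamma, 8 / 7)
  expect_error(mergeRegions(ss = numeric(), n = integer()), "no regions")
  expect_error(mergeRegions(ss = c(1, 2), n = c(4, 4), p = c(3, 5)),
               "different numbers of features")

  Y <- randomY(20, 4, seed = 5)
  p <- partitionDiversity(Y, equalGrid(4, 5))
  expect_equal(mergeRegions(list(p))$sdGamma, sdGamma(p))
})

test_that("sums of squares rescale to the published diversity quantities", {
  expect_equal(sdFromSS(1.66, 625), 1.66 / 624)
  expect_equal(round(sdFromSS(1.66, 625), 4), 0.0027)
  expect_equal(meanAlphaSD(0.26, 25, 25), 0.26 / 600)
  expect_equal(round(meanAlphaSD(0.26, 25, 25), 5), 0.00043)
  expect_equal(ssPercent(1.40, 1.66), 100 * 1.40 / 1.66)
  # identical to the mean of per-community SD_alpha under equal m
  Y <- randomY(30, 2, seed = 3)
  p <- partitionDiversity(Y, equalGrid(5, 6))
  expect_equal(p@sdAlphaMean, meanAlphaSD(ssAlpha(p), 5, 6),
               tolerance = 1e-12)
})
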