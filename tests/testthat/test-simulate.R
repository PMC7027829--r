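test_that("leaf-spectra library has the expected size, determinism and bounds", {
  lib <- makeLeafSpectra(S = 3, I = 5, seed = 10)
  expect_equal(nrow(lib$spectra), 15)
  expect_equal(ncol(lib$spectra), 201)
  expect_true(all(lib$spectra >= 0 & lib$spectra <= 1))
  expect_identical(lib$spectra, makeLeafSpectra(S = 3, I = 5, seed = 10)$spectra)
  expect_false(identical(lib$spectra,
                         makeLeafSpectra(S = 3, I = 5, seed = 11)$spectra))

  # zero individual variation collapses each species to one spectrum
  lib0 <- makeLeafSpectra(seed = 1, individualSd = 0)
  for (s in 1:3) {
    rows <- lib0$spectra[lib0$species == s, ]
    expect_lt(max(abs(sweep(rows, 2, rows[1, ]))), 1e-12)
  }

  expect_error(makeLeafSpectra(S = 0), "positive")
  expect_error(makeLeafSpectra(wavelengths = c(400, 500)), "10 wavelengths")
})

test_that("conspecific spectra are closer than heterospecific spectra", {
  for (seed in c(1, 5, 12)) {
    lib <- makeLeafSpectra(seed = seed)
    D <- as.matrix(dist(lib$spectra))
    same <- outer(lib$species, lib$species, "==") & upper.tri(D)
    diff <- outer(lib$species, lib$species, "!=") & upper.tri(D)
    expect_lt(mean(D[same]), mean(D[diff]))
  }
})

test_that("high-beta landscapes are species-pure within communities", {
  lib <- makeLeafSpectra(seed = 2)
  scn <- assembleHighBeta(lib, seed = 2)
  expect_equal(dim(scn@cube), c(25L, 25L, 201L))
  expect_equal(nCommunities(scn@grid), 25)
  lab <- communityAssignment(scn@grid)
  spp <- as.vector(t(scn@pixelSpecies))     # row-major, like the grid
  for (k in unique(lab))
    expect_equal(length(unique(spp[lab == k])), 1)

  # single-species probabilities produce a single-species landscape
  mono <- assembleHighBeta(lib, speciesProbs = c(1, 0, 0), seed = 3)
  expect_true(all(mono@pixelSpecies == 1))

  expect_error(assembleHighBeta(lib, speciesProbs = c(0.5, 0.5)),
               "3 species")
  expect_error(assembleHighBeta(lib, speciesProbs = c(0.6, 0.3, 0.2)),
               "sum to 1")
  expect_error(assembleHighBeta(lib, rows = 24, cols = 25), "divisible")
})

test_that("the pixel permutation preserves gamma exactly and collapses beta", {
  pair <- simulateScenarioPair(seed = 4)
  fh <- scenarioFeatures(pair$high)
  fl <- scenarioFeatures(pair$low)
  # identical multiset of spectra
  Yh <- featureValues(fh$Y); Yl <- featureValues(fl$Y)
  expect_identical(Yh[do.call(order, as.data.frame(Yh)), ],
                   Yl[do.call(order, as.data.frame(Yl)), ])
  ph <- partitionDiversity(fh$Y, fh$grid)
  pl <- partitionDiversity(fl$Y, fl$grid)
  expect_identical(ssGamma(ph), ssGamma(pl))
  expect_lt(ssBeta(pl), ssBeta(ph))

  # forced identity permutation is a no-op
  ident <- permuteToLowBeta(pair$high, permutation = seq_len(625))
  expect_identical(reflectance(ident@cube), reflectance(pair$high@cube))
  expect_identical(ident@pixelSpecies, pair$high@pixelSpecies)

  expect_error(permuteToLowBeta(pair$low), "high_beta")
  expect_error(permuteToLowBeta(pair$high, permutation = rep(1L, 625)),
               "permutation")
})

test_that("zero intra-individual variation makes high-beta alpha diversity exactly zero", {
  lib <- makeLeafSpectra(S = 3, I = 1, seed = 6, individualSd = 0)
  scn <- assembleHighBeta(lib, seed = 6)
  f <- scenarioFeatures(scn)
  p <- partitionDiversity(f$Y, f$grid)
  expect_equal(ssAlpha(p), 0)
})

test_that("truth tables record pixel identities and community labels", {
  pair <- simulateScenarioPair(seed = 8, rows = 10, cols = 10)
  path <- tempfile(fileext = ".csv")
  writeTruthTable(pair$high, path)
  tt <- read.csv(path)
  expect_equal(nrow(tt), 100)
  expect_setequal(names(tt), c("row", "col", "community", "species",
                               "individual"))
  expect_true(all(tt$species %in% 1:3))
})
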