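test_that("trimBands keeps exactly the bands inside keepRange and outside drop windows", {
  cube <- spectralCube(array(0.4, c(2, 2, 6)),
                       c(380, 400, 1400, 1800, 2400, 2450))
  out <- trimBands(cube)   # default water windows + 400-2400 nm keep range
  expect_identical(wavelengths(out), c(400, 2400))
  expect_equal(dim(out)[3], 2)

  # identity: no drop windows, unbounded keep range
  same <- trimBands(cube, dropWindows = list(), keepRange = c(-Inf, Inf))
  expect_identical(wavelengths(same), wavelengths(cube))
  expect_identical(reflectance(same), reflectance(cube))

  # idempotence with the same windows
  twice <- trimBands(out)
  expect_identical(wavelengths(twice), wavelengths(out))

  expect_error(trimBands(cube, dropWindows = list(c(300, 2500))),
               "empty spectrum")
})

test_that("Savitzky-Golay filter reproduces cubic polynomials and is linear", {
  wl <- seq(400, 700, by = 10)   # 31 uniform bands
  poly <- 1e-9 * (wl - 550)^3 + 1e-5 * (wl - 550)^2 + 0.3
  cube <- makeTestCube(2, 2, wl, function(r, c, w) poly)
  sm <- savgolSmooth(cube, order = 3, window = 7)
  expect_lt(max(abs(reflectance(sm) - reflectance(cube))), 1e-9)

  # constant spectrum untouched
  flat <- makeTestCube(2, 2, wl, function(r, c, w) rep(0.5, length(w)))
  expect_lt(max(abs(reflectance(savgolSmooth(flat)) - 0.5)), 1e-12)

  # single spike is attenuated
  spike <- rep(0, 31); spike[16] <- 1
  sc <- makeTestCube(1, 2, wl, function(r, c, w) spike)
  expect_lt(max(reflectance(savgolSmooth(sc))), 1)

  # linearity: filter(aX + bY) = a filter(X) + b filter(Y)
  set.seed(4)
  x <- runif(31); y <- runif(31)
  cx <- makeTestCube(1, 2, wl, function(r, c, w) x)
  cy <- makeTestCube(1, 2, wl, function(r, c, w) y)
  cxy <- makeTestCube(1, 2, wl, function(r, c, w) 2 * x - 0.5 * y)
  lhs <- reflectance(savgolSmooth(cxy))
  rhs <- 2 * reflectance(savgolSmooth(cx)) - 0.5 * reflectance(savgolSmooth(cy))
  expect_lt(max(abs(lhs - rhs)), 1e-9)
})

test_that("smoothing respects wavelength gaps and validates parameters", {
  # two segments separated by a wide gap: smoothing one segment must not
  # depend on the other
  wl <- c(seq(400, 500, 10), seq(900, 1000, 10))
  set.seed(9)
  a <- runif(11); b1 <- runif(11); b2 <- runif(11)
  c1 <- makeTestCube(1, 2, wl, function(r, c, w) c(a, b1))
  c2 <- makeTestCube(1, 2, wl, function(r, c, w) c(a, b2))
  s1 <- reflectance(savgolSmooth(c1))[1, 1, 1:11]
  s2 <- reflectance(savgolSmooth(c2))[1, 1, 1:11]
  expect_equal(s1, s2, tolerance = 1e-12)

  expect_error(savgolSmooth(c1, window = 6), "odd")
  expect_error(savgolSmooth(c1, order = 7, window = 7), "greater than order")
  wlShort <- c(seq(400, 430, 10), seq(900, 1000, 10))   # 4-band segment
  cs <- makeTestCube(1, 2, wlShort, function(r, c, w) runif(length(w)))
  expect_error(savgolSmooth(cs), "segment 1 \\(400-430 nm\\)")
})

test_that("NDVI arithmetic, band snapping and undefined pixels", {
  wl <- c(670, 800)
  refl <- array(0, c(1, 3, 2))
  refl[1, 1, ] <- c(0.1, 0.5)     # (0.5-0.1)/0.6
  refl[1, 2, ] <- c(0.3, 0.3)     # flat -> 0
  refl[1, 3, ] <- c(0, 0)         # undefined
  cube <- spectralCube(refl, wl)
  nd <- computeNDVI(cube)
  expect_equal(nd[1, 1], 0.4 / 0.6)
  expect_equal(nd[1, 2], 0)
  expect_true(is.na(nd[1, 3]))

  masked <- maskVegetation(cube, threshold = 0.5)
  expect_identical(as.vector(validMask(masked)), c(TRUE, FALSE, FALSE))

  expect_error(computeNDVI(cube, redWl = 660, nirWl = 680),
               "same band")
})

test_that("NDVI masking keeps pixels at the threshold and only shrinks validity", {
  cube <- makeTestCube(1, 3)
  nd <- matrix(c(0.9, 0.79, 0.8), 1, 3)
  m <- maskVegetation(cube, ndviMap = nd, threshold = 0.8)
  expect_identical(as.vector(validMask(m)), c(TRUE, FALSE, TRUE))

  all_ok <- maskVegetation(cube, ndviMap = nd, threshold = -1)
  expect_true(all(validMask(all_ok)))

  none <- maskVegetation(cube, ndviMap = nd, threshold = 1)
  expect_error(cubeToFeatures(none), "no valid pixels")
})

test_that("shade mask removes the stated NIR quantile and is monotone", {
  wl <- c(670, 800)
  refl <- array(0, c(10, 10, 2))
  refl[, , 1] <- 0.01
  refl[, , 2] <- matrix(1:100, 10, 10)   # NIR 1..100
  cube <- spectralCube(refl, wl)
  sm <- shadeMask(cube, quantile = 0.2)
  expect_equal(sum(validMask(sm)), 80)
  removed <- sort(refl[, , 2][!validMask(sm)])
  expect_equal(removed, 1:20)            # the darkest fifth

  none <- shadeMask(cube, quantile = 0)
  expect_equal(sum(validMask(none)), 100)

  # applying twice never re-adds pixels
  sm2 <- shadeMask(sm, quantile = 0.2)
  expect_true(all(validMask(sm2) <= validMask(sm)))
})

test_that("brightness normalization yields unit-norm, scale-invariant spectra", {
  wl <- c(500, 600)
  refl <- array(0, c(1, 3, 2))
  refl[1, 1, ] <- c(3, 4)
  refl[1, 2, ] <- c(0.6, 0.8)      # already unit norm
  refl[1, 3, ] <- c(30, 40)        # scalar multiple of pixel 1
  cube <- brightnessNormalize(spectralCube(refl, wl))
  expect_equal(reflectance(cube)[1, 1, ], c(0.6, 0.8))
  expect_equal(reflectance(cube)[1, 2, ], c(0.6, 0.8))
  expect_equal(reflectance(cube)[1, 1, ], reflectance(cube)[1, 3, ])

  # unit norms across a random cube
  set.seed(11)
  rc <- spectralCube(array(runif(5 * 4 * 6, 0.1, 0.9), c(5, 4, 6)),
                     seq(400, 900, 100))
  norms <- apply(reflectance(brightnessNormalize(rc)), c(1, 2),
                 function(s) sqrt(sum(s^2)))
  expect_lt(max(abs(norms - 1)), 1e-12)

  zero <- array(0, c(2, 1, 2))
  zero[1, 1, ] <- c(0.1, 0.2)
  expect_error(brightnessNormalize(spectralCube(zero, wl)),
               "all-zero spectrum at valid pixel \\(row 1, col 0\\)")
})

test_that("composed default pipeline preserves pixel count on a clean cube", {
  pair <- simulateScenarioPair(seed = 3, rows = 10, cols = 10)
  cube <- pair$high@cube
  out <- brightnessNormalize(
    maskVegetation(savgolSmooth(trimBands(cube))))
  expect_equal(sum(validMask(out)), prod(dim(cube)[1:2]))
})
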