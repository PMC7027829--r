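# Synthetic-landscape simulator: parametric leaf reflectance spectra for S
# species x I individuals, a high-beta landscape assembled by drawing one
# species per community, and a gamma-preserving pixel permutation that
# collapses the among-community structure (the low-beta scenario).

# Base optical parameters for three temperate broadleaf-like species:
# a sigmoid red edge between a low visible continuum and a NIR plateau,
# Gaussian pigment absorptions near 445/670 nm, Gaussian water absorptions
# near 1450/1940 nm, and a broad SWIR decline. Chosen so canopy NDVI stays
# comfortably above the 0.8 vegetation threshold and so interspecific
# spectral distances exceed intraspecific ones.
speciesDefaults <- function() {
  data.frame(
    visBase  = c(0.18, 0.17, 0.19),
    nir      = c(0.55, 0.40, 0.49),
    redEdge  = c(708, 714, 704),
    d445     = c(0.145, 0.125, 0.150),
    d670     = c(0.208, 0.173, 0.216),
    w1450    = c(0.38, 0.68, 0.30),
    w1940    = c(0.52, 0.80, 0.45),
    swirDrop = c(0.22, 0.40, 0.15)
  )
}

# Gaussian-jitter clamped at +/- 2 sd; keeps individual spectra physical
# (no negative reflectance, NDVI above the vegetation threshold).
rnormClamped <- function(n, sd) {
  x <- stats::rnorm(n, 0, sd)
  pmin(pmax(x, -2 * sd), 2 * sd)
}

leafSpectrum <- function(wl, p) {
  r0 <- p$visBase + (p$nir - p$visBase) * stats::plogis((wl - p$redEdge) / 20)
  pig <- p$d445 * exp(-0.5 * ((wl - 445) / 45)^2) +
         p$d670 * exp(-0.5 * ((wl - 670) / 40)^2)
  water <- p$w1450 * exp(-0.5 * ((wl - 1450) / 60)^2) +
           p$w1940 * exp(-0.5 * ((wl - 1940) / 90)^2)
  swir <- 1 - p$swirDrop * stats::plogis((wl - 2150) / 180)
  r <- (r0 - pig) * pmax(1 - water, 0) * swir
  pmin(pmax(r, 0), 1)
}

#' Generate a library of synthetic leaf spectra
#'
#' Builds `S x I` labelled reflectance spectra: each species gets a base
#' spectrum (continuum minus Gaussian pigment and water absorption features
#' plus a near-infrared plateau), and each individual perturbs the species
#' parameters with smooth, clamped Gaussian jitter. Deterministic given
#' `seed`. Under default parameters, individuals of one species are closer
#' to conspecifics than to heterospecifics (mean Euclidean distance).
#'
#' @param S number of species (>= 1).
#' @param I individuals per species (>= 1).
#' @param wavelengths nm grid (default 400-2400 nm at 10 nm, 201 bands).
#' @param seed integer seed.
#' @param individualSd relative standard deviation of individual-level
#'   parameter jitter (default 0.06; 0 makes all conspecifics identical).
#' @return list with `spectra` (`S*I x bands` matrix, rows labelled
#'   `sp<s>_ind<i>`), `species` and `individual` integer labels,
#'   `wavelengths`, and the per-species parameter table `params`.
#' @export
makeLeafSpectra <- function(S = 3L, I = 5L,
                            wavelengths = seq(400, 2400, by = 10),
                            seed = 1L, individualSd = 0.06) {
  if (S < 1L || I < 1L) stop("S and I must be positive")
  if (length(wavelengths) < 10L)
    stop("at least 10 wavelengths are required")
  base <- speciesDefaults()
  params <- base[((seq_len(S) - 1L) %% 3L) + 1L, , drop = FALSE]
  # additional species beyond the three base types get deterministic shifts
  tier <- (seq_len(S) - 1L) %/% 3L
  params$nir <- params$nir * (1 + 0.05 * tier)
  params$redEdge <- params$redEdge + 3 * tier
  params$w1450 <- pmin(params$w1450 * (1 + 0.08 * tier), 0.9)
  rownames(params) <- paste0("sp", seq_len(S))

  set.seed(seed)
  spectra <- matrix(0, S * I, length(wavelengths))
  species <- rep(seq_len(S), each = I)
  individual <- rep(seq_len(I), times = S)
  for (r in seq_len(S * I)) {
    p <- as.list(params[species[r], ])
    p$nir <- p$nir * (1 + rnormClamped(1, individualSd))
    wj <- 1 + rnormClamped(1, individualSd)
    p$w1450 <- p$w1450 * wj
    p$w1940 <- min(p$w1940 * wj, 0.9)
    pj <- 1 + rnormClamped(1, individualSd / 3)
    p$d445 <- p$d445 * pj
    p$d670 <- p$d670 * pj
    p$redEdge <- p$redEdge + rnormClamped(1, 2 * individualSd / 0.06)
    spectra[r, ] <- leafSpectrum(wavelengths, p)
  }
  rownames(spectra) <- paste0("sp", species, "_ind", individual)
  colnames(spectra) <- sprintf("%gnm", wavelengths)
  list(spectra = spectra, species = species, individual = individual,
       wavelengths = wavelengths, params = params)
}

#' Assemble a high-beta landscape
#'
#' Tiles a `rows x cols` image into square communities of `plotPx x plotPx`
#' pixels, draws one species per community from `speciesProbs`, and fills
#' each pixel with a spectrum drawn uniformly, with replacement, from that
#' species' individuals. Communities are therefore spectrally pure at the
#' species level, so most spectral variation sits among communities (high
#' beta diversity, low alpha diversity).
#'
#' Species-per-community and individual-per-pixel draws use separate
#' substreams of the master seed.
#'
#' @param library a leaf-spectra library from [makeLeafSpectra()].
#' @param rows,cols image dimensions in pixels (default 25 x 25).
#' @param plotPx community side length in pixels (default 5); must divide
#'   `rows` and `cols`.
#' @param speciesProbs per-species selection probabilities, summing to 1
#'   (default `c(0.60, 0.35, 0.05)`).
#' @param seed integer seed.
#' @return a [LandscapeScenario] with `scenario = "high_beta"`.
#' @export
assembleHighBeta <- function(library, rows = 25L, cols = 25L, plotPx = 5L,
                             speciesProbs = c(0.60, 0.35, 0.05), seed = 1L) {
  S <- max(library$species)
  I <- max(library$individual)
  if (length(speciesProbs) != S)
    stop(sprintf("speciesProbs has %d entries but the library holds %d species",
                 length(speciesProbs), S))
  if (abs(sum(speciesProbs) - 1) > 1e-9)
    stop("speciesProbs must sum to 1")
  if (rows %% plotPx != 0L || cols %% plotPx != 0L)
    stop("rows and cols must be divisible by plotPx")

  coords <- cbind(row = rep(0:(rows - 1L), each = cols),
                  col = rep(0:(cols - 1L), times = rows))   # row-major
  grid <- makeCommunityGrid(coords, plotPx, c(rows, cols))
  q <- nCommunities(grid)
  lab <- communityAssignment(grid)

  set.seed(substreamSeed(seed, 0L, 0L))
  commSpecies <- sample.int(S, q, replace = TRUE, prob = speciesProbs)

  n <- rows * cols
  pixSpecies <- integer(n)
  pixIndividual <- integer(n)
  for (k in seq_len(q)) {
    px <- which(lab == k)
    set.seed(substreamSeed(seed, 1L, k))
    pixIndividual[px] <- sample.int(I, length(px), replace = TRUE)
    pixSpecies[px] <- commSpecies[k]
  }
  libRow <- (pixSpecies - 1L) * I + pixIndividual
  refl <- array(NA_real_, c(rows, cols, length(library$wavelengths)))
  flat <- library$spectra[libRow, , drop = FALSE]
  # scatter row-major pixel list into the array
  rIdx <- coords[, 1L] + 1L
  cIdx <- coords[, 2L] + 1L
  for (b in seq_len(dim(refl)[3L]))
    refl[cbind(rIdx, cIdx, b)] <- flat[, b]
  spMat <- matrix(NA_integer_, rows, cols); spMat[cbind(rIdx, cIdx)] <- pixSpecies
  inMat <- matrix(NA_integer_, rows, cols); inMat[cbind(rIdx, cIdx)] <- pixIndividual

  new("LandscapeScenario",
      cube = spectralCube(refl, library$wavelengths),
      pixelSpecies = spMat, pixelIndividual = inMat,
      grid = grid, scenario = "high_beta", seed = as.integer(seed))
}

#' Permute a high-beta landscape into its low-beta counterpart
#'
#' Moves the pixels of a high-beta scenario to uniformly random positions,
#' keeping the community tiling fixed. The multiset of pixel spectra is
#' preserved exactly, so gamma diversity is identical to the input; the
#' among-community (beta) component collapses toward its random-mixing
#' expectation while the within-community (alpha) component rises.
#'
#' @param scn a `"high_beta"` [LandscapeScenario].
#' @param seed integer seed for the permutation.
#' @param permutation optional explicit permutation of `1..n` (row-major
#'   pixel order), e.g. the identity; overrides the random draw.
#' @return a [LandscapeScenario] with `scenario = "low_beta"`.
#' @export
permuteToLowBeta <- function(scn, seed = 1L, permutation = NULL) {
  if (scn@scenario != "high_beta")
    stop("input scenario must be 'high_beta'")
  d <- dim(scn@cube)
  n <- d[1L] * d[2L]
  if (is.null(permutation)) {
    set.seed(substreamSeed(seed, 2L, 0L))
    permutation <- sample.int(n)
  }
  if (length(permutation) != n || anyDuplicated(permutation))
    stop("permutation must be a permutation of 1..n")
  rows <- d[1L]; cols <- d[2L]
  rIdx <- rep(1:rows, each = cols)   # row-major pixel order
  cIdx <- rep(1:cols, times = rows)
  src <- cbind(rIdx[permutation], cIdx[permutation])
  dst <- cbind(rIdx, cIdx)
  refl <- reflectance(scn@cube)
  out <- refl
  for (b in seq_len(d[3L]))
    out[cbind(dst, b)] <- refl[cbind(src, b)]
  spMat <- scn@pixelSpecies; spMat[dst] <- scn@pixelSpecies[src]
  inMat <- scn@pixelIndividual; inMat[dst] <- scn@pixelIndividual[src]
  new("LandscapeScenario",
      cube = spectralCube(out, wavelengths(scn@cube)),
      pixelSpecies = spMat, pixelIndividual = inMat,
      grid = scn@grid, scenario = "low_beta", seed = as.integer(seed))
}

#' Simulate a matched high-beta / low-beta scenario pair
#'
#' Convenience wrapper: generates a leaf-spectra library, assembles the
#' high-beta landscape, and derives the low-beta landscape by pixel
#' permutation. The two scenarios share the exact multiset of spectra and
#' hence identical gamma diversity.
#'
#' @param seed master integer seed.
#' @param ... passed to [makeLeafSpectra()] and [assembleHighBeta()]
#'   (`S`, `I`, `wavelengths`, `individualSd`, `rows`, `cols`, `plotPx`,
#'   `speciesProbs`).
#' @return list with elements `high` and `low` ([LandscapeScenario]s) and
#'   `library`.
#' @export
simulateScenarioPair <- function(seed = 1L, ...) {
  dots <- list(...)
  libArgs <- dots[names(dots) %in% c("S", "I", "wavelengths", "individualSd")]
  asmArgs <- dots[names(dots) %in% c("rows", "cols", "plotPx", "speciesProbs")]
  lib <- do.call(makeLeafSpectra, c(list(seed = seed), libArgs))
  high <- do.call(assembleHighBeta, c(list(library = lib, seed = seed),
                                      asmArgs))
  low <- permuteToLowBeta(high, seed = seed)
  list(high = high, low = low, library = lib)
}

#' Pixel-by-feature matrix and grid of a simulated scenario
#'
#' @param scn a [LandscapeScenario]
#' @return list with `Y` (a [FeatureMatrix] of raw band reflectance) and
#'   `grid` (the scenario's [CommunityGrid], row-aligned with `Y`).
#' @export
scenarioFeatures <- function(scn) {
  list(Y = cubeToFeatures(scn@cube), grid = scn@grid)
}

setMethod("show", "LandscapeScenario", function(object) {
  d <- dim(object@cube)
  cat(sprintf("LandscapeScenario (%s): %d x %d pixels, %d communities, seed %d\n",
              object@scenario, d[1L], d[2L], nCommunities(object@grid),
              object@seed))
})

#' Write a scenario's truth table
#'
#' Per-pixel CSV (`row,col,community,species,individual`) for validating
#' downstream analyses against the simulated ground truth.
#'
#' @param scn a [LandscapeScenario]
#' @param path output CSV path.
#' @return the path, invisibly
#' @export
writeTruthTable <- function(scn, path) {
  d <- dim(scn@cube)
  coords <- cbind(row = rep(0:(d[1L] - 1L), each = d[2L]),
                  col = rep(0:(d[2L] - 1L), times = d[1L]))
  df <- data.frame(coords,
                   community = communityAssignment(scn@grid),
                   species = scn@pixelSpecies[coords + 1L],
                   individual = scn@pixelIndividual[coords + 1L])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
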