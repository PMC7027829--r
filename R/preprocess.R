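# Cube preprocessing: band trimming, Savitzky-Golay smoothing, NDVI and
# shade masking, brightness normalization. Each step takes and returns a
# SpectralCube; masking steps only ever shrink the valid set.

#' Default atmospheric water-absorption windows (nm)
#'
#' The two water-vapour absorption regions customarily removed from airborne
#' reflectance spectra, plus the default retained range excluding the noisy
#' spectrum ends.
#' @export
waterAbsorptionWindows <- function() {
  list(c(1340, 1455), c(1790, 1955))
}

#' Remove spectral bands by wavelength window
#'
#' Keeps exactly the bands whose center wavelength lies inside `keepRange`
#' (inclusive) and inside none of the `dropWindows` (inclusive). Band order
#' is preserved. Defaults drop the two atmospheric water-absorption windows
#' and the noisy ends below 400 and above 2400 nm.
#'
#' @param cube a [SpectralCube]
#' @param dropWindows list of length-2 numeric vectors `c(lo, hi)` in nm.
#' @param keepRange length-2 numeric `c(lo, hi)` in nm.
#' @return a [SpectralCube] containing the retained bands.
#' @examples
#' cube <- spectralCube(array(0.4, c(2, 2, 6)),
#'                      c(380, 400, 1400, 1800, 2400, 2450))
#' wavelengths(trimBands(cube))   # 400 and 2400 survive
#' @export
trimBands <- function(cube, dropWindows = waterAbsorptionWindows(),
                      keepRange = c(400, 2400)) {
  wl <- wavelengths(cube)
  for (w in dropWindows)
    if (length(w) != 2L || w[1L] > w[2L])
      stop("each drop window must be c(lo, hi) with lo <= hi")
  if (keepRange[1L] > keepRange[2L])
    stop("keepRange must satisfy lo <= hi")
  keep <- wl >= keepRange[1L] & wl <= keepRange[2L]
  for (w in dropWindows)
    keep <- keep & !(wl >= w[1L] & wl <= w[2L])
  if (!any(keep))
    stop("empty spectrum: every band falls in a dropped window or outside keepRange")
  spectralCube(reflectance(cube)[, , keep, drop = FALSE], wl[keep],
               validMask = validMask(cube),
               geotransform = geotransform(cube))
}

# Savitzky-Golay smoothing matrix for a segment of length L: column i is the
# filter response to the i-th unit impulse, so S %*% y smooths y with
# least-squares polynomial edge handling (signal::sgolayfilt convention).
sgMatrix <- function(L, order, window) {
  S <- vapply(seq_len(L), function(i) {
    e <- numeric(L); e[i] <- 1
    as.numeric(signal::sgolayfilt(e, p = order, n = window))
  }, numeric(L))
  S
}

#' Savitzky-Golay smoothing along the spectral axis
#'
#' Replaces every pixel's spectrum by its Savitzky-Golay filtered version.
#' Smoothing is applied independently within each contiguous wavelength
#' segment (segments are delimited by the gaps left after [trimBands()]),
#' never across a gap. Edge samples use the standard least-squares
#' polynomial fits, so any polynomial of degree at most `order` is
#' reproduced exactly at every sample.
#'
#' @param cube a [SpectralCube]
#' @param order polynomial order of the filter (default 3).
#' @param window filter window length in bands; odd and greater than
#'   `order` (default 7).
#' @param gapFactor spacing threshold (multiple of the median band spacing)
#'   beyond which two neighbouring bands are treated as separate segments.
#' @return a smoothed [SpectralCube]
#' @export
savgolSmooth <- function(cube, order = 3L, window = 7L, gapFactor = 2.5) {
  if (window %% 2L == 0L || window <= order)
    stop("window must be odd and greater than order")
  refl <- reflectance(cube)
  d <- dim(refl)
  segs <- wavelengthSegments(wavelengths(cube), gapFactor)
  flat <- matrix(refl, nrow = d[1L] * d[2L], ncol = d[3L])
  for (s in seq_along(segs)) {
    idx <- segs[[s]]
    if (length(idx) < window) {
      wl <- wavelengths(cube)[idx]
      stop(sprintf(
        "segment %d (%g-%g nm) has %d bands, fewer than the filter window %d",
        s, min(wl), max(wl), length(idx), window))
    }
    S <- sgMatrix(length(idx), order, window)
    flat[, idx] <- flat[, idx, drop = FALSE] %*% t(S)
  }
  spectralCube(array(flat, d), wavelengths(cube),
               validMask = validMask(cube),
               geotransform = geotransform(cube))
}

#' Normalized difference vegetation index
#'
#' `NDVI = (NIR - red) / (NIR + red)` per pixel, using the band whose center
#' wavelength is nearest to each requested wavelength. Pixels whose two
#' reflectances sum to zero get `NA` (undefined).
#'
#' @param cube a [SpectralCube]
#' @param redWl,nirWl requested red and near-infrared wavelengths in nm
#'   (defaults 670 and 800).
#' @return numeric `rows x cols` matrix of NDVI in `[-1, 1]`, `NA` where
#'   undefined.
#' @export
computeNDVI <- function(cube, redWl = 670, nirWl = 800) {
  wl <- wavelengths(cube)
  ir <- nearestBand(wl, redWl)
  in_ <- nearestBand(wl, nirWl)
  if (ir == in_)
    stop(sprintf(
      "red (%g nm) and NIR (%g nm) requests snap to the same band (%g nm)",
      redWl, nirWl, wl[ir]))
  d <- dim(cube)
  red <- matrix(reflectance(cube)[, , ir], d[1L], d[2L])
  nir <- matrix(reflectance(cube)[, , in_], d[1L], d[2L])
  den <- nir + red
  out <- (nir - red) / den
  out[!is.na(den) & den == 0] <- NA_real_
  out
}

#' Mask non-vegetated pixels by NDVI threshold
#'
#' Flags invalid every pixel with `NDVI < threshold` (strict: pixels exactly
#' at the threshold are kept) or with undefined NDVI. Reflectance values are
#' untouched.
#'
#' @param cube a [SpectralCube]
#' @param ndviMap optional precomputed NDVI matrix; computed from
#'   `redWl`/`nirWl` when absent.
#' @param threshold NDVI cutoff in `[-1, 1]` (default 0.8).
#' @param redWl,nirWl band requests passed to [computeNDVI()].
#' @return a [SpectralCube] with the shrunken valid mask.
#' @export
maskVegetation <- function(cube, ndviMap = NULL, threshold = 0.8,
                           redWl = 670, nirWl = 800) {
  if (threshold < -1 || threshold > 1)
    stop("threshold must lie in [-1, 1]")
  if (is.null(ndviMap))
    ndviMap <- computeNDVI(cube, redWl, nirWl)
  if (!identical(dim(ndviMap), dim(validMask(cube))))
    stop("ndviMap shape must equal the cube's spatial shape")
  keep <- !is.na(ndviMap) & ndviMap >= threshold
  validMask(cube) <- keep
  cube
}

#' Optional shade mask by NIR-reflectance quantile
#'
#' Flags invalid the currently valid pixels whose near-infrared reflectance
#' falls below the given quantile of the valid-pixel NIR distribution. A
#' coarse, optional shadow filter; off by default in the pipeline.
#'
#' @param cube a [SpectralCube]
#' @param nirWl NIR wavelength request in nm (default 800).
#' @param quantile fraction in `[0, 1)` of the NIR distribution to remove.
#' @return a [SpectralCube] with the shrunken valid mask.
#' @export
shadeMask <- function(cube, nirWl = 800, quantile = 0.2) {
  if (quantile < 0 || quantile >= 1)
    stop("quantile must lie in [0, 1)")
  mask <- validMask(cube)
  if (!any(mask))
    stop("no valid pixels to apply a shade mask to")
  nir <- reflectance(cube)[, , nearestBand(wavelengths(cube), nirWl)]
  thr <- stats::quantile(nir[mask], probs = quantile, names = FALSE)
  keep <- is.na(nir) | nir >= thr        # NA pixels are already invalid
  validMask(cube) <- keep
  cube
}

#' Brightness-normalize all valid spectra
#'
#' Divides every valid pixel's spectrum by its Euclidean (L2) norm across
#' bands, removing per-pixel illumination/brightness scaling; output spectra
#' have unit norm. Two pixels that are scalar multiples of each other become
#' identical. Invalid pixels are untouched.
#'
#' @param cube a [SpectralCube]
#' @return a [SpectralCube] of unit-norm spectra.
#' @export
brightnessNormalize <- function(cube) {
  refl <- reflectance(cube)
  d <- dim(refl)
  flat <- matrix(refl, nrow = d[1L] * d[2L], ncol = d[3L])
  vidx <- which(validMask(cube))          # column-major linear pixel index
  norms <- sqrt(rowSums(flat[vidx, , drop = FALSE]^2))
  if (any(norms == 0)) {
    bad <- vidx[norms == 0][1L]
    stop(sprintf(
      "all-zero spectrum at valid pixel (row %d, col %d); cannot normalize",
      (bad - 1L) %% d[1L], (bad - 1L) %/% d[1L]))
  }
  flat[vidx, ] <- flat[vidx, , drop = FALSE] / norms
  spectralCube(array(flat, d), wavelengths(cube),
               validMask = validMask(cube),
               geotransform = geotransform(cube))
}
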