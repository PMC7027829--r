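#' @import methods
NULL

#' Hyperspectral reflectance cube
#'
#' An in-memory imaging-spectroscopy scene: a `rows x cols x bands` array of
#' unitless surface reflectance, the band-center wavelengths in nanometres,
#' and a per-pixel logical mask flagging usable (vegetated, unshaded) pixels.
#' An optional six-number affine geotransform (GDAL convention: origin x,
#' pixel width, row rotation, origin y, column rotation, pixel height) maps
#' pixel indices to map coordinates.
#'
#' @slot reflectance three-dimensional numeric array, indexed (row, col, band).
#' @slot wavelengths strictly increasing numeric vector of band-center
#'   wavelengths in nm; one entry per band.
#' @slot validMask logical matrix of the spatial shape; `TRUE` marks a usable
#'   pixel.
#' @slot geotransform numeric of length 6 (affine transform) or length 0 when
#'   the cube is not georeferenced.
#' @slot nodata numeric sentinel for missing reflectance (length 0 when unset).
#'
#' @seealso [spectralCube()], [readENVI()], [trimBands()],
#'   [brightnessNormalize()]
#' @export
setClass("SpectralCube",
  slots = c(
    reflectance  = "array",
    wavelengths  = "numeric",
    validMask    = "matrix",
    geotransform = "numeric",
    nodata       = "numeric"
  )
)

setValidity("SpectralCube", function(object) {
  d <- dim(object@reflectance)
  msg <- character()
  if (length(d) != 3L)
    msg <- c(msg, "reflectance must be a rows x cols x bands array")
  else {
    if (length(object@wavelengths) != d[3L])
      msg <- c(msg, "number of wavelengths must equal the band count")
    if (!identical(dim(object@validMask), d[1:2]))
      msg <- c(msg, "validMask shape must equal the spatial shape")
  }
  if (length(object@wavelengths) > 1L &&
      any(diff(object@wavelengths) <= 0))
    msg <- c(msg, "wavelengths must be strictly increasing")
  if (!is.logical(object@validMask))
    msg <- c(msg, "validMask must be logical")
  if (!(length(object@geotransform) %in% c(0L, 6L)))
    msg <- c(msg, "geotransform must have length 0 or 6")
  if (length(msg)) msg else TRUE
})

#' Pixel-by-feature matrix
#'
#' The central object of the diversity partition: a matrix `Y` whose `n` rows
#' are pixels and whose `p` columns are spectral features (reflectance bands,
#' principal-component scores, or user-supplied vegetation indices), together
#' with the (row, col) image coordinates of each pixel. All sums of squares
#' and contribution indices are computed on this object.
#'
#' @slot values numeric `n x p` matrix; column names are the feature labels.
#' @slot pixelIndex integer `n x 2` matrix of 0-based (row, col) image
#'   coordinates; rows must be unique.
#'
#' @seealso [featureMatrix()], [cubeToFeatures()], [partitionDiversity()]
#' @export
setClass("FeatureMatrix",
  slots = c(values = "matrix", pixelIndex = "matrix")
)

setValidity("FeatureMatrix", function(object) {
  msg <- character()
  if (!is.numeric(object@values))
    msg <- c(msg, "values must be numeric")
  if (anyNA(object@values) || any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite with no missing entries")
  if (nrow(object@values) < 2L)
    msg <- c(msg, "a FeatureMatrix needs at least 2 pixels")
  if (ncol(object@values) < 1L)
    msg <- c(msg, "a FeatureMatrix needs at least 1 feature")
  if (!identical(nrow(object@pixelIndex), nrow(object@values)) ||
      ncol(object@pixelIndex) != 2L)
    msg <- c(msg, "pixelIndex must be an n x 2 matrix")
  else if (anyDuplicated(object@pixelIndex))
    msg <- c(msg, "pixelIndex entries must be unique")
  if (length(msg)) msg else TRUE
})

#' Community tiling of an image
#'
#' Assignment of pixels to square, non-overlapping communities (the sampling
#' units of the alpha/beta partition, standing in for vegetation inventory
#' plots). The assignment vector is aligned with the rows of a
#' [FeatureMatrix]; pixels falling in incomplete edge tiles carry `NA`.
#'
#' @slot assignment integer vector of community labels in `1..q`, `NA` for
#'   unassigned pixels; one entry per pixel row.
#' @slot q number of communities.
#' @slot counts integer vector (length `q`) of assigned pixels per community.
#' @slot plotSizePx side length of the square tiles, in pixels.
#' @slot origin 0-based (row, col) of the tiling origin.
#'
#' @seealso [makeCommunityGrid()], [partitionDiversity()],
#'   [rarefiedPartition()]
#' @export
setClass("CommunityGrid",
  slots = c(
    assignment = "integer",
    q          = "integer",
    counts     = "integer",
    plotSizePx = "integer",
    origin     = "integer"
  )
)

setValidity("CommunityGrid", function(object) {
  msg <- character()
  if (length(object@q) != 1L || object@q < 1L)
    msg <- c(msg, "q must be a single positive integer")
  a <- object@assignment[!is.na(object@assignment)]
  if (length(a) && (min(a) < 1L || max(a) > object@q))
    msg <- c(msg, "assignment labels must lie in 1..q")
  if (length(object@counts) != object@q)
    msg <- c(msg, "counts must have one entry per community")
  else if (sum(object@counts) != length(a))
    msg <- c(msg, "counts must sum to the number of assigned pixels")
  if (length(msg)) msg else TRUE
})

#' Principal-component model of a spectral feature space
#'
#' Covariance PCA (divisor `n - 1`) of a column-centered [FeatureMatrix],
#' with type-1 ("distance") scaling: scores are `(Y - center) %*% loadings`,
#' so pairwise Euclidean distances among pixels are preserved at full rank.
#' Loading signs follow a deterministic convention (the largest-magnitude
#' element of each column is positive, ties broken by lowest row index).
#'
#' @slot center per-feature means of the training matrix.
#' @slot loadings orthonormal eigenvector matrix (feature x component).
#' @slot eigenvalues component variances, non-increasing, clipped at zero.
#' @slot relativeEigenvalues `eigenvalues / sum(eigenvalues)`; equal to the
#'   per-component feature contributions to spectral gamma diversity
#'   (FCSD-gamma) when the components are used as features. All zero when the
#'   training matrix has rank 0.
#' @slot n number of training pixels.
#'
#' @seealso [fitPCA()], [transformPCA()]
#' @export
setClass("SpectralPCA",
  slots = c(
    center              = "numeric",
    loadings            = "matrix",
    eigenvalues         = "numeric",
    relativeEigenvalues = "numeric",
    n                   = "integer"
  )
)

setValidity("SpectralPCA", function(object) {
  msg <- character()
  if (length(object@eigenvalues) &&
      any(diff(object@eigenvalues) > 1e-9 * max(object@eigenvalues, 1)))
    msg <- c(msg, "eigenvalues must be non-increasing")
  if (any(object@eigenvalues < 0))
    msg <- c(msg, "eigenvalues must be non-negative")
  tot <- sum(object@relativeEigenvalues)
  if (tot > 0 && abs(tot - 1) > 1e-9)
    msg <- c(msg, "relative eigenvalues must sum to 1")
  if (length(msg)) msg else TRUE
})

#' Complete spectral-diversity partition of a region
#'
#' Result bundle of the additive variance partition `SS_gamma = SS_beta +
#' SS_alpha`: total, among-community and within-community sums of squares and
#' the derived spectral diversities, plus local (per-pixel, per-community)
#' and feature contributions. Contribution indices whose denominator sum of
#' squares is zero are reported as `NA` (undefined), never as 0/0.
#'
#' @slot ssGamma total sum of squares of the region.
#' @slot sdGamma spectral gamma diversity, `ssGamma / (n - 1)`.
#' @slot ssBeta among-community sum of squares.
#' @slot sdBeta spectral beta diversity, `ssBeta / (n - 1)`.
#' @slot ssBetaK per-community contribution to `ssBeta` (length `q`).
#' @slot ssAlpha within-community sum of squares, summed over communities.
#' @slot ssAlphaK per-community within sum of squares (length `q`).
#' @slot sdAlphaK per-community spectral alpha diversity,
#'   `ssAlphaK / (m - 1)`.
#' @slot sdAlphaMean mean of `sdAlphaK` over communities.
#' @slot lcsdGamma per-pixel local contribution to gamma diversity (sums
#'   to 1).
#' @slot lcsdBeta per-community local contribution to beta diversity (sums
#'   to 1 when `ssBeta > 0`).
#' @slot fcsdGamma per-feature contribution to gamma diversity (sums to 1).
#' @slot fcsdBeta per-feature contribution to beta diversity.
#' @slot fcsdAlpha `q x p` matrix of per-feature contributions to each
#'   community's alpha diversity (rows sum to 1 where `ssAlphaK > 0`).
#' @slot n,p,q,m dimensions: pixels, features, communities, pixels per
#'   community (`q` and `m` are `NA` for a gamma-only partition).
#'
#' @seealso [partitionDiversity()], [spectralGamma()], [spectralBeta()],
#'   [spectralAlpha()]
#' @export
setClass("SpectralPartition",
  slots = c(
    ssGamma     = "numeric",
    sdGamma     = "numeric",
    ssBeta      = "numeric",
    sdBeta      = "numeric",
    ssBetaK     = "numeric",
    ssAlpha     = "numeric",
    ssAlphaK    = "numeric",
    sdAlphaK    = "numeric",
    sdAlphaMean = "numeric",
    lcsdGamma   = "numeric",
    lcsdBeta    = "numeric",
    fcsdGamma   = "numeric",
    fcsdBeta    = "numeric",
    fcsdAlpha   = "matrix",
    n           = "integer",
    p           = "integer",
    q           = "integer",
    m           = "integer"
  )
)

#' Rarefied spectral-diversity partition
#'
#' Aggregate of [SpectralPartition] results over repeated random subsamples
#' of `mMin` pixels per community, used when communities have unequal numbers
#' of valid pixels (the exact partition assumes equal community size).
#'
#' @slot mMin number of pixels drawn per community (the minimum valid-pixel
#'   count across retained communities).
#' @slot repeats number of random subsamples.
#' @slot seed master random seed.
#' @slot perRepeat list of per-repeat [SpectralPartition] objects.
#' @slot aggregate elementwise mean (or median) of the per-repeat results,
#'   as a [SpectralPartition]; per-pixel contributions are averaged only over
#'   the repeats in which the pixel was drawn (`NA` if never drawn).
#' @slot aggregation `"mean"` or `"median"`.
#'
#' @seealso [rarefiedPartition()]
#' @export
setClass("RarefactionResult",
  slots = c(
    mMin        = "integer",
    repeats     = "integer",
    seed        = "integer",
    perRepeat   = "list",
    aggregate   = "SpectralPartition",
    aggregation = "character"
  )
)

setValidity("RarefactionResult", function(object) {
  msg <- character()
  if (object@repeats < 1L)
    msg <- c(msg, "repeats must be >= 1")
  if (!object@aggregation %in% c("mean", "median"))
    msg <- c(msg, "aggregation must be 'mean' or 'median'")
  if (length(object@perRepeat) != object@repeats)
    msg <- c(msg, "perRepeat must hold one partition per repeat")
  if (length(msg)) msg else TRUE
})

#' Simulated landscape scenario
#'
#' A synthetic hyperspectral landscape assembled from a library of leaf
#' spectra: a [SpectralCube], the species and individual identity behind each
#' pixel, and the community tiling. The `"high_beta"` scenario assigns one
#' species per community; the `"low_beta"` scenario is derived from it by a
#' random permutation of pixel positions, which preserves the multiset of
#' spectra (hence gamma diversity) exactly while collapsing the
#' among-community structure.
#'
#' @slot cube the simulated [SpectralCube].
#' @slot pixelSpecies integer matrix (rows x cols) of species labels.
#' @slot pixelIndividual integer matrix (rows x cols) of individual labels
#'   within species.
#' @slot grid the [CommunityGrid] tiling.
#' @slot scenario `"high_beta"` or `"low_beta"`.
#' @slot seed integer seed the scenario was generated from.
#'
#' @seealso [assembleHighBeta()], [permuteToLowBeta()],
#'   [simulateScenarioPair()]
#' @export
setClass("LandscapeScenario",
  slots = c(
    cube            = "SpectralCube",
    pixelSpecies    = "matrix",
    pixelIndividual = "matrix",
    grid            = "CommunityGrid",
    scenario        = "character",
    seed            = "integer"
  )
)

setValidity("LandscapeScenario", function(object) {
  if (!object@scenario %in% c("high_beta", "low_beta"))
    return("scenario must be 'high_beta' or 'low_beta'")
  TRUE
})
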