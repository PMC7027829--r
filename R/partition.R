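# The variance-partitioning core: total (gamma) sum of squares of the pixel
# x feature matrix, its additive among-community (beta) and within-community
# (alpha) components, and the local (LCSD) and feature (FCSD) contribution
# indices. Deviations are always taken from explicitly materialized column
# means (two-pass), which keeps the additivity identity stable in floating
# point.

#' Tile an image into square communities
#'
#' Assigns pixels to non-overlapping `plotSizePx x plotSizePx` square
#' communities, numbered row-major from the tiling origin (image top-left by
#' default). Tiles not fully inside the image are discarded; pixels falling
#' in a discarded strip (or before the origin) get `NA`.
#'
#' @param pixels a [FeatureMatrix], or an `n x 2` matrix of 0-based
#'   (row, col) pixel coordinates.
#' @param plotSizePx side length of the square communities, in pixels.
#' @param imageShape length-2 integer `c(rows, cols)` of the image.
#' @param origin 0-based (row, col) tiling origin (default `c(0, 0)`).
#' @return a [CommunityGrid]; `communityCounts()` gives the per-community
#'   valid-pixel counts.
#' @examples
#' coords <- as.matrix(expand.grid(row = 0:24, col = 0:24))
#' grid <- makeCommunityGrid(coords, 5, c(25, 25))
#' nCommunities(grid)       # 25 communities of 25 pixels
#' @export
makeCommunityGrid <- function(pixels, plotSizePx, imageShape,
                              origin = c(0L, 0L)) {
  if (plotSizePx < 1L) stop("plotSizePx must be >= 1")
  coords <- if (is(pixels, "FeatureMatrix")) pixelCoords(pixels)
            else as.matrix(pixels)
  imageShape <- as.integer(imageShape)
  nTileR <- (imageShape[1L] - origin[1L]) %/% plotSizePx
  nTileC <- (imageShape[2L] - origin[2L]) %/% plotSizePx
  if (nTileR < 1L || nTileC < 1L)
    stop(sprintf("image (%d x %d) holds no complete %d x %d plot",
                 imageShape[1L], imageShape[2L], plotSizePx, plotSizePx))
  r <- coords[, 1L] - origin[1L]
  c_ <- coords[, 2L] - origin[2L]
  tr <- r %/% plotSizePx
  tc <- c_ %/% plotSizePx
  ok <- r >= 0L & c_ >= 0L & tr < nTileR & tc < nTileC
  lab <- ifelse(ok, tr * nTileC + tc + 1L, NA_integer_)
  q <- nTileR * nTileC
  counts <- tabulate(lab[!is.na(lab)], nbins = q)
  new("CommunityGrid",
      assignment = as.integer(lab),
      q = as.integer(q),
      counts = as.integer(counts),
      plotSizePx = as.integer(plotSizePx),
      origin = as.integer(origin))
}

#' Build a CommunityGrid from explicit labels
#'
#' Wraps a per-pixel community label vector (aligned with the rows of a
#' [FeatureMatrix]) into a [CommunityGrid], for layouts not generated by
#' square tiling (e.g. read from a feature table). Labels are mapped to
#' `1..q` in sorted order of their unique values.
#'
#' @param assignment vector of community labels, one per pixel (`NA` =
#'   unassigned).
#' @param plotSizePx optional plot side length the labels correspond to.
#' @return a [CommunityGrid]
#' @export
communityGrid <- function(assignment, plotSizePx = NA_integer_) {
  lev <- sort(unique(assignment[!is.na(assignment)]))
  if (!length(lev)) stop("no assigned pixels")
  lab <- match(assignment, lev)
  new("CommunityGrid",
      assignment = as.integer(lab),
      q = length(lev),
      counts = tabulate(lab, nbins = length(lev)),
      plotSizePx = as.integer(plotSizePx),
      origin = c(0L, 0L))
}

#' @rdname CommunityGrid-class
#' @aliases communityAssignment,CommunityGrid-method
#' @export
setMethod("communityAssignment", "CommunityGrid", function(x) x@assignment)

#' @rdname CommunityGrid-class
#' @aliases communityCounts,CommunityGrid-method
#' @export
setMethod("communityCounts", "CommunityGrid", function(x) x@counts)

#' @rdname CommunityGrid-class
#' @aliases nCommunities,CommunityGrid-method
#' @export
setMethod("nCommunities", "CommunityGrid", function(x) x@q)

setMethod("show", "CommunityGrid", function(object) {
  cat(sprintf(
    "CommunityGrid: %d communities (%d x %d px plots), %d assigned pixels\n",
    object@q, object@plotSizePx, object@plotSizePx,
    sum(!is.na(object@assignment))))
  rng <- range(object@counts)
  cat(sprintf("  pixels per community: %d-%d%s\n", rng[1L], rng[2L],
              if (rng[1L] == rng[2L]) " (equal)" else " (unequal; rarefy)"))
})

asValues <- function(Y) {
  if (is(Y, "FeatureMatrix")) featureValues(Y) else as.matrix(Y)
}

#' Spectral gamma diversity of a region
#'
#' Total variation of the pixel x feature matrix: squared deviations of
#' every entry from its column mean are summed into the total sum of squares
#' `SS_gamma`; spectral gamma diversity is `SD_gamma = SS_gamma / (n - 1)`,
#' the total variance. Also returns each pixel's local contribution
#' (`lcsdGamma`, its share of `SS_gamma`; the squared distance of the pixel
#' to the region centroid, normalized) and each feature's contribution
#' (`fcsdGamma`).
#'
#' @param Y a [FeatureMatrix] or numeric matrix (`n >= 2` rows).
#' @return list with `ssGamma`, `sdGamma`, `lcsdGamma`, `fcsdGamma`,
#'   `ssGammaJ` (per feature), `ssGammaI` (per pixel). Contribution indices
#'   are `NA` when `SS_gamma = 0`.
#' @examples
#' spectralGamma(matrix(c(0, 2, 0, 2), ncol = 1))   # SS = 4, SD = 4/3
#' @export
spectralGamma <- function(Y) {
  X <- asValues(Y)
  n <- nrow(X)
  if (n < 2L) stop("gamma diversity requires at least 2 pixels")
  s <- sweep(X, 2L, colMeans(X))^2
  ssJ <- colSums(s)
  ssI <- rowSums(s)
  ss <- sum(ssJ)
  list(ssGamma = ss,
       sdGamma = ss / (n - 1),
       lcsdGamma = safeShare(ssI, ss),
       fcsdGamma = safeShare(ssJ, ss),
       ssGammaJ = ssJ,
       ssGammaI = ssI)
}

communityMeans <- function(X, k, q) {
  m <- tabulate(k, nbins = q)
  rowsum(X, k, reorder = TRUE) / m
}

checkPartitionGrid <- function(X, grid) {
  k <- communityAssignment(grid)
  if (length(k) != nrow(X))
    stop("grid assignment length must equal the number of pixels")
  if (anyNA(k))
    stop("unassigned (NA) pixels present; subset the matrix to assigned pixels first")
  cnt <- tabulate(k, nbins = nCommunities(grid))
  if (any(cnt == 0L))
    stop("community(ies) without pixels: ",
         paste(which(cnt == 0L), collapse = ", "),
         "; drop them (or rarefy with a floor) before partitioning")
  if (length(unique(cnt)) > 1L)
    stop("communities have unequal pixel counts; use rarefiedPartition() ",
         "to subsample an equal number of pixels per community")
  k
}

#' Spectral beta diversity: among-community component
#'
#' Among-community variation: each community centroid's squared deviation
#' from the global column means, weighted by the (equal) community size `m`.
#' `LCSD_beta` gives each community's share of `SS_beta` — how spectrally
#' distinct its composition is from the average community — and `FCSD_beta`
#' each feature's share.
#'
#' @param Y a [FeatureMatrix] or numeric matrix.
#' @param grid a [CommunityGrid] with equal community sizes covering every
#'   row of `Y`.
#' @return list with `ssBeta`, `sdBeta`, `ssBetaK`, `lcsdBeta`, `fcsdBeta`,
#'   `centroids` (`q x p` matrix of community means). With a single
#'   community, `ssBeta = 0` and the contributions are `NA`.
#' @export
spectralBeta <- function(Y, grid) {
  X <- asValues(Y)
  k <- checkPartitionGrid(X, grid)
  q <- nCommunities(grid)
  m <- nrow(X) / q
  cen <- communityMeans(X, k, q)
  skj <- sweep(cen, 2L, colMeans(X))^2
  ssK <- m * rowSums(skj)
  ssJ <- m * colSums(skj)
  ss <- sum(ssK)
  list(ssBeta = ss,
       sdBeta = ss / (nrow(X) - 1),
       ssBetaK = ssK,
       lcsdBeta = safeShare(ssK, ss),
       fcsdBeta = safeShare(ssJ, ss),
       centroids = cen)
}

#' Spectral alpha diversity: within-community component
#'
#' Within-community variation: squared deviations of each pixel from its own
#' community centroid. Per community `k`, `SS_alpha_k` sums those deviations
#' and `SD_alpha_k = SS_alpha_k / (m - 1)` is the community's spectral
#' variance, comparable across communities of different sizes. `FCSD_alpha`
#' resolves each community's alpha diversity into per-feature shares.
#'
#' @param Y a [FeatureMatrix] or numeric matrix.
#' @param grid a [CommunityGrid] with equal community sizes.
#' @param centroids optional precomputed `q x p` community-mean matrix.
#' @param ssOnly if `TRUE`, allow single-pixel communities and report their
#'   `SD_alpha_k` as `NA` instead of erroring.
#' @return list with `ssAlpha`, `ssAlphaK`, `sdAlphaK`, `sdAlphaMean`,
#'   `fcsdAlpha` (`q x p`).
#' @export
spectralAlpha <- function(Y, grid, centroids = NULL, ssOnly = FALSE) {
  X <- asValues(Y)
  k <- checkPartitionGrid(X, grid)
  q <- nCommunities(grid)
  m <- nrow(X) / q
  if (m < 2 && !ssOnly)
    stop("SD_alpha is undefined for single-pixel communities ",
         "(set ssOnly = TRUE for sums of squares only)")
  if (is.null(centroids)) centroids <- communityMeans(X, k, q)
  dev2 <- (X - centroids[k, , drop = FALSE])^2
  ssJK <- rowsum(dev2, k, reorder = TRUE)          # q x p
  ssK <- rowSums(ssJK)
  sdK <- if (m >= 2) ssK / (m - 1) else rep(NA_real_, q)
  fa <- ssJK / ssK                                  # rows with ssK=0 -> NaN
  fa[ssK <= 0, ] <- NA_real_
  list(ssAlpha = sum(ssK),
       ssAlphaK = ssK,
       sdAlphaK = sdK,
       sdAlphaMean = mean(sdK),
       fcsdAlpha = fa)
}

#' Full additive spectral-diversity partition
#'
#' Runs the gamma, beta and alpha partitions and packages them into a
#' [SpectralPartition], asserting the additivity identity
#' `SS_gamma = SS_beta + SS_alpha` to a relative tolerance of 1e-9 (a
#' violation raises an internal-consistency error rather than returning
#' silently).
#'
#' @param Y a [FeatureMatrix] or numeric matrix of pixels x features.
#' @param grid a [CommunityGrid] assigning every row of `Y`; all communities
#'   must hold the same number of pixels (rarefy first if not).
#' @return a [SpectralPartition]
#' @examples
#' Y <- matrix(c(0, 0, 2, 2), ncol = 1)
#' grid <- communityGrid(c(1, 1, 2, 2))
#' partitionDiversity(Y, grid)    # SS_gamma 4 = SS_beta 4 + SS_alpha 0
#' @export
partitionDiversity <- function(Y, grid) {
  X <- asValues(Y)
  g <- spectralGamma(X)
  b <- spectralBeta(X, grid)
  a <- spectralAlpha(X, grid, centroids = b$centroids, ssOnly = TRUE)
  tol <- 1e-9 * max(g$ssGamma, .Machine$double.eps)
  if (abs(g$ssGamma - b$ssBeta - a$ssAlpha) > tol)
    stop(sprintf(
      "internal consistency failure: SS_gamma (%g) != SS_beta (%g) + SS_alpha (%g)",
      g$ssGamma, b$ssBeta, a$ssAlpha))
  q <- nCommunities(grid)
  m <- nrow(X) %/% q
  new("SpectralPartition",
      ssGamma = g$ssGamma, sdGamma = g$sdGamma,
      ssBeta = b$ssBeta, sdBeta = b$sdBeta, ssBetaK = b$ssBetaK,
      ssAlpha = a$ssAlpha, ssAlphaK = a$ssAlphaK,
      sdAlphaK = a$sdAlphaK, sdAlphaMean = a$sdAlphaMean,
      lcsdGamma = g$lcsdGamma, lcsdBeta = b$lcsdBeta,
      fcsdGamma = g$fcsdGamma, fcsdBeta = b$fcsdBeta,
      fcsdAlpha = a$fcsdAlpha,
      n = nrow(X), p = ncol(X), q = as.integer(q), m = as.integer(m))
}

#' @rdname SpectralPartition-class
#' @aliases ssGamma,SpectralPartition-method
#' @export
setMethod("ssGamma", "SpectralPartition", function(x) x@ssGamma)
#' @rdname SpectralPartition-class
#' @export
setMethod("sdGamma", "SpectralPartition", function(x) x@sdGamma)
#' @rdname SpectralPartition-class
#' @export
setMethod("ssBeta", "SpectralPartition", function(x) x@ssBeta)
#' @rdname SpectralPartition-class
#' @export
setMethod("sdBeta", "SpectralPartition", function(x) x@sdBeta)
#' @rdname SpectralPartition-class
#' @export
setMethod("ssAlpha", "SpectralPartition", function(x) x@ssAlpha)
#' @rdname SpectralPartition-class
#' @export
setMethod("sdAlpha", "SpectralPartition", function(x) x@sdAlphaK)
#' @rdname SpectralPartition-class
#' @export
setMethod("lcsdGamma", "SpectralPartition", function(x) x@lcsdGamma)
#' @rdname SpectralPartition-class
#' @export
setMethod("lcsdBeta", "SpectralPartition", function(x) x@lcsdBeta)
#' @rdname SpectralPartition-class
#' @export
setMethod("fcsdGamma", "SpectralPartition", function(x) x@fcsdGamma)
#' @rdname SpectralPartition-class
#' @export
setMethod("fcsdBeta", "SpectralPartition", function(x) x@fcsdBeta)
#' @rdname SpectralPartition-class
#' @export
setMethod("fcsdAlpha", "SpectralPartition", function(x) x@fcsdAlpha)

#' @rdname SpectralPartition-class
#' @param object a `SpectralPartition`
#' @param ... ignored
#' @export
setMethod("summary", "SpectralPartition", function(object, ...) {
  data.frame(
    component = c("gamma", "beta", "alpha"),
    ss = c(object@ssGamma, object@ssBeta, object@ssAlpha),
    pctOfGamma = 100 * c(1, object@ssBeta / object@ssGamma,
                         object@ssAlpha / object@ssGamma),
    sd = c(object@sdGamma, object@sdBeta, object@sdAlphaMean),
    row.names = NULL)
})

setMethod("show", "SpectralPartition", function(object) {
  cat(sprintf(
    "SpectralPartition: n = %d pixels, p = %d features, q = %d communities of m = %d\n",
    object@n, object@p, object@q, object@m))
  s <- summary(object)
  cat(sprintf("  SS_gamma = %.4g (SD_gamma = %.4g)\n",
              object@ssGamma, object@sdGamma))
  cat(sprintf("  SS_beta  = %.4g (%.1f%%; SD_beta = %.4g)\n",
              object@ssBeta, s$pctOfGamma[2L], object@sdBeta))
  cat(sprintf("  SS_alpha = %.4g (%.1f%%; mean SD_alpha = %.4g)\n",
              object@ssAlpha, s$pctOfGamma[3L], object@sdAlphaMean))
})

#' Rescale sums of squares to spectral diversities
#'
#' The scaling identities relating a sum of squares to the corresponding
#' spectral diversity: `sdFromSS()` divides a total (gamma or beta) sum of
#' squares by `n - 1` pixels; `meanAlphaSD()` converts the pooled
#' within-community sum of squares of `q` equal communities of `m` pixels to
#' the mean per-community alpha diversity `SS_alpha / (q (m - 1))` (equal,
#' under equal `m`, to the mean of the per-community `SD_alpha_k`);
#' `ssPercent()` expresses a component as a percentage of the total. These
#' let regional summaries be recomputed from published sums of squares and
#' pixel counts alone.
#'
#' @param ss a sum of squares.
#' @param n total number of pixels.
#' @return a spectral diversity (variance-scale) value.
#' @export
sdFromSS <- function(ss, n) {
  if (n < 2) stop("n must be >= 2")
  ss / (n - 1)
}

#' @rdname sdFromSS
#' @param ssAlpha pooled within-community sum of squares.
#' @param q number of communities.
#' @param m pixels per community.
#' @export
meanAlphaSD <- function(ssAlpha, q, m) {
  if (m < 2) stop("m must be >= 2")
  ssAlpha / (q * (m - 1))
}

#' @rdname sdFromSS
#' @param ssComponent component (beta or alpha) sum of squares.
#' @param ssTotal total sum of squares.
#' @export
ssPercent <- function(ssComponent, ssTotal) {
  100 * ssComponent / ssTotal
}

#' Pool gamma diversity across adjacent regions
#'
#' Adds the regional total sums of squares and divides by the pooled pixel
#' count minus one. Exact only when every region's deviations were taken
#' from the joint mean (region-level `SD_gamma` values themselves cannot be
#' averaged); provided as the standard aggregation rule for adjacent regions
#' sharing a feature space, with that caveat.
#'
#' @param partitions optional list of [SpectralPartition] objects.
#' @param ss,n numeric vectors of per-region total sums of squares and pixel
#'   counts (alternative to `partitions`).
#' @param p optional per-region feature counts, checked for agreement.
#' @return list with `ssGamma`, `sdGamma`, `n`.
#' @examples
#' mergeRegions(ss = c(4, 4), n = c(4, 4))   # SS 8, SD 8/7
#' @export
mergeRegions <- function(partitions = NULL, ss = NULL, n = NULL, p = NULL) {
  if (!is.null(partitions)) {
    if (!length(partitions)) stop("no regions to merge")
    ss <- vapply(partitions, ssGamma, numeric(1))
    n <- vapply(partitions, function(x) x@n, integer(1))
    p <- vapply(partitions, function(x) x@p, integer(1))
  }
  if (is.null(ss) || !length(ss)) stop("no regions to merge")
  if (length(ss) != length(n)) stop("ss and n must have equal length")
  if (!is.null(p) && length(unique(p)) > 1L)
    stop("regions use different numbers of features and cannot be merged")
  list(ssGamma = sum(ss), sdGamma = sum(ss) / (sum(n) - 1), n = sum(n))
}
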