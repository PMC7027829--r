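# Spectral feature extraction: covariance PCA with type-1 (distance
# preserving) scaling. The eigendecomposition itself is delegated to
# stats::prcomp; this module adds the deterministic sign convention, the
# relative eigenvalues, and the truncation/contract checks.

#' Fit a principal-component model (type-1 scaling)
#'
#' Eigen-decomposition of the covariance matrix (divisor `n - 1`) of the
#' column-centered feature matrix. Components are ordered by decreasing
#' eigenvalue; tiny negative eigenvalues from floating point are clipped to
#' zero. Each loading column is sign-fixed so that its largest-magnitude
#' element is positive (ties broken by lowest feature index), making runs
#' reproducible. When the features are later replaced by the full set of
#' component scores, the per-component relative eigenvalues equal the
#' feature contributions to spectral gamma diversity.
#'
#' @param Y a [FeatureMatrix] (or bare numeric matrix) of pixels x features.
#' @return a [SpectralPCA]
#' @examples
#' Y <- featureMatrix(rbind(c(0, 0), c(1, 0), c(0, 1), c(1, 1)))
#' fitPCA(Y)@relativeEigenvalues   # 0.5, 0.5
#' @export
fitPCA <- function(Y) {
  X <- if (is(Y, "FeatureMatrix")) featureValues(Y) else as.matrix(Y)
  if (nrow(X) < 2L)
    stop("PCA requires at least 2 pixels")
  if (anyNA(X) || any(!is.finite(X)))
    stop("PCA input must be finite")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pmax(pc$sdev^2, 0)
  load <- pc$rotation
  # deterministic sign convention
  for (j in seq_len(ncol(load))) {
    i <- which.max(abs(load[, j]))       # first index wins ties
    if (load[i, j] < 0) load[, j] <- -load[, j]
  }
  rel <- if (sum(ev) > 0) ev / sum(ev) else rep(0, length(ev))
  if (sum(ev) == 0)
    warning("rank-0 matrix: all pixels identical, all eigenvalues zero")
  new("SpectralPCA", center = pc$center, loadings = load,
      eigenvalues = ev, relativeEigenvalues = rel, n = nrow(X))
}

#' Project pixels onto principal components
#'
#' Computes type-1 scaled scores `(Y - center) %*% loadings`, truncated to
#' the first `nComponents` columns. With all components retained, pairwise
#' Euclidean distances among pixels equal those of the centered input, so
#' every sum-of-squares quantity of the diversity partition is unchanged by
#' the rotation.
#'
#' `nComponents` and `varianceTarget` are mutually exclusive; the latter
#' retains the smallest number of leading components whose cumulative
#' relative eigenvalue reaches the target.
#'
#' @param model a [SpectralPCA] from [fitPCA()].
#' @param Y a [FeatureMatrix] with the same features the model was fit on.
#' @param nComponents number of leading components to keep (default: all).
#' @param varianceTarget fraction in (0, 1]; alternative to `nComponents`.
#' @return a [FeatureMatrix] of scores with labels `PC1..PCk`.
#' @export
transformPCA <- function(model, Y, nComponents = NULL,
                         varianceTarget = NULL) {
  X <- if (is(Y, "FeatureMatrix")) featureValues(Y) else as.matrix(Y)
  if (ncol(X) != nrow(model@loadings))
    stop("feature count does not match the fitted model")
  pmax_ <- ncol(model@loadings)
  if (!is.null(nComponents) && !is.null(varianceTarget))
    stop("nComponents and varianceTarget are mutually exclusive")
  if (!is.null(varianceTarget)) {
    if (varianceTarget <= 0 || varianceTarget > 1)
      stop("varianceTarget must lie in (0, 1]")
    nComponents <- which(cumsum(model@relativeEigenvalues) >=
                           varianceTarget - 1e-12)[1L]
    if (is.na(nComponents)) nComponents <- pmax_
  }
  if (is.null(nComponents)) nComponents <- pmax_
  if (nComponents < 1L || nComponents > pmax_)
    stop(sprintf("nComponents must lie in 1..%d", pmax_))
  sc <- sweep(X, 2L, model@center) %*%
    model@loadings[, seq_len(nComponents), drop = FALSE]
  colnames(sc) <- paste0("PC", seq_len(nComponents))
  pix <- if (is(Y, "FeatureMatrix")) pixelCoords(Y) else NULL
  featureMatrix(sc, pix)
}

setMethod("show", "SpectralPCA", function(object) {
  k <- min(6L, length(object@eigenvalues))
  cat(sprintf("SpectralPCA: %d components fit on %d pixels\n",
              length(object@eigenvalues), object@n))
  cat("  relative eigenvalues:",
      paste(sprintf("%.3f", object@relativeEigenvalues[seq_len(k)]),
            collapse = ", "),
      if (length(object@eigenvalues) > k) "...", "\n")
})
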