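# Rarefaction: the exact partition assumes the same number of pixels m in
# every community. When masking leaves unequal valid-pixel counts, an equal
# number m_min (the minimum count) is drawn without replacement from every
# community, the partition run on the draw, and the process repeated; the
# reported result is the elementwise mean (or median) over repeats.

#' Rarefied spectral-diversity partition
#'
#' Repeatedly subsamples `mMin` pixels (the minimum valid-pixel count over
#' retained communities) from every community without replacement, runs
#' [partitionDiversity()] on each draw, and aggregates elementwise across
#' repeats. Per-pixel gamma contributions are aggregated only over the
#' repeats in which the pixel was drawn (`NA` if never drawn).
#'
#' Randomness is fully determined by `seed`: each repeat x community pair
#' draws from its own substream (a counter scheme on the master seed), so
#' results do not depend on community iteration order and rerunning with the
#' same seed is bit-identical.
#'
#' @param Y a [FeatureMatrix] or numeric matrix.
#' @param grid a [CommunityGrid]; counts may be unequal. Rows of `Y` with
#'   `NA` assignment are ignored.
#' @param repeats number of random subsamples (default 30).
#' @param seed master integer seed.
#' @param aggregation `"mean"` (default) or `"median"`.
#' @param minFraction optional floor in (0, 1]: communities whose
#'   valid-pixel count is below this fraction of the plot capacity
#'   (`plotSizePx^2` when known, else the maximum observed count) are
#'   dropped before `mMin` is computed.
#' @return a [RarefactionResult]
#' @export
rarefiedPartition <- function(Y, grid, repeats = 30L, seed = 1L,
                              aggregation = c("mean", "median"),
                              minFraction = NULL) {
  aggregation <- match.arg(aggregation)
  if (repeats < 1L) stop("repeats must be >= 1")
  X <- asValues(Y)
  k <- communityAssignment(grid)
  if (length(k) != nrow(X))
    stop("grid assignment length must equal the number of pixels")
  rows <- which(!is.na(k))
  k <- k[rows]
  q <- nCommunities(grid)
  counts <- tabulate(k, nbins = q)

  retained <- seq_len(q)
  if (!is.null(minFraction)) {
    capacity <- if (!is.na(grid@plotSizePx)) grid@plotSizePx^2
                else max(counts)
    retained <- which(counts >= minFraction * capacity)
    if (!length(retained))
      stop("floor filtering removed every community")
  }
  tooSmall <- retained[counts[retained] < 2L]
  if (length(tooSmall))
    stop("community(ies) with fewer than 2 valid pixels: ",
         paste(tooSmall, collapse = ", "),
         "; mask them out or drop them with minFraction")
  mMin <- min(counts[retained])
  qr <- length(retained)

  rowsByComm <- lapply(retained, function(kk) rows[k == kk])
  n <- nrow(X)
  lcsdDraws <- matrix(NA_real_, n, repeats)
  per <- vector("list", repeats)
  subgrid <- communityGrid(rep(seq_len(qr), each = mMin))
  for (r in seq_len(repeats)) {
    take <- integer(qr * mMin)
    for (ci in seq_len(qr)) {
      set.seed(substreamSeed(seed, r, retained[ci]))
      pool <- rowsByComm[[ci]]
      take[(ci - 1L) * mMin + seq_len(mMin)] <-
        if (length(pool) == mMin) pool else sample(pool, mMin)
    }
    part <- partitionDiversity(X[take, , drop = FALSE], subgrid)
    per[[r]] <- part
    lcsdDraws[take, r] <- part@lcsdGamma
  }

  agg <- if (aggregation == "mean") {
    function(v) mean(v)
  } else function(v) stats::median(v)
  aggVec <- function(get) {
    vals <- vapply(per, get, numeric(length(get(per[[1L]]))))
    if (is.null(dim(vals))) return(agg(vals))
    apply(vals, 1L, agg)
  }
  aggMat <- function(get) {
    arr <- vapply(per, get, get(per[[1L]]))
    apply(arr, c(1L, 2L), agg)
  }
  drawn <- rowSums(!is.na(lcsdDraws)) > 0L
  lcsdG <- rep(NA_real_, n)
  lcsdG[drawn] <- apply(lcsdDraws[drawn, , drop = FALSE], 1L,
                        function(v) agg(v[!is.na(v)]))

  aggregate <- new("SpectralPartition",
    ssGamma = aggVec(function(x) x@ssGamma),
    sdGamma = aggVec(function(x) x@sdGamma),
    ssBeta = aggVec(function(x) x@ssBeta),
    sdBeta = aggVec(function(x) x@sdBeta),
    ssBetaK = aggVec(function(x) x@ssBetaK),
    ssAlpha = aggVec(function(x) x@ssAlpha),
    ssAlphaK = aggVec(function(x) x@ssAlphaK),
    sdAlphaK = aggVec(function(x) x@sdAlphaK),
    sdAlphaMean = aggVec(function(x) x@sdAlphaMean),
    lcsdGamma = lcsdG,
    lcsdBeta = aggVec(function(x) x@lcsdBeta),
    fcsdGamma = aggVec(function(x) x@fcsdGamma),
    fcsdBeta = aggVec(function(x) x@fcsdBeta),
    fcsdAlpha = aggMat(function(x) x@fcsdAlpha),
    n = qr * mMin, p = ncol(X), q = qr, m = mMin)

  nm <- as.character(retained)   # original community labels
  names(aggregate@ssBetaK) <- names(aggregate@lcsdBeta) <- nm
  names(aggregate@ssAlphaK) <- names(aggregate@sdAlphaK) <- nm
  rownames(aggregate@fcsdAlpha) <- nm

  new("RarefactionResult",
      mMin = as.integer(mMin), repeats = as.integer(repeats),
      seed = as.integer(seed), perRepeat = per,
      aggregate = aggregate, aggregation = aggregation)
}

setMethod("show", "RarefactionResult", function(object) {
  cat(sprintf(
    "RarefactionResult: %d repeats of m_min = %d pixels/community (%s aggregate)\n",
    object@repeats, object@mMin, object@aggregation))
  show(object@aggregate)
})
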