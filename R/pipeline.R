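# End-to-end workflow: preprocess -> feature extraction -> community tiling
# -> (rarefied) diversity partition, with tables, maps and a provenance log
# written to an output directory. All randomness flows from the config seed.

#' Default pipeline configuration
#'
#' Returns the full configuration list with documented defaults; a user
#' config (list or YAML file) is merged over it. Keys mirror the pipeline
#' stages: `drop_windows`, `keep_range`, `sg_order`, `sg_window`,
#' `ndvi_threshold`, `red_wl`, `nir_wl`, `shade_mask` (`enabled`,
#' `quantile`), `n_components`/`variance_target`, `plot_size_px`,
#' `rarefaction` (`repeats`, `aggregation`, `min_fraction`), `seed`,
#' `out_dir`, `input`.
#'
#' @return named list of defaults
#' @export
defaultConfig <- function() {
  list(
    input = NULL,
    out_dir = NULL,
    drop_windows = waterAbsorptionWindows(),
    keep_range = c(400, 2400),
    sg_order = 3L,
    sg_window = 7L,
    ndvi_threshold = 0.8,
    red_wl = 670,
    nir_wl = 800,
    shade_mask = list(enabled = FALSE, quantile = 0.2),
    n_components = NULL,
    variance_target = NULL,
    plot_size_px = NULL,
    rarefaction = list(repeats = 30L, aggregation = "mean",
                       min_fraction = NULL),
    seed = 1L
  )
}

mergeConfig <- function(user) {
  cfg <- defaultConfig()
  for (k in names(user)) {
    if (is.list(cfg[[k]]) && is.list(user[[k]]) &&
        !is.null(names(cfg[[k]])))
      cfg[[k]][names(user[[k]])] <- user[[k]]
    else cfg[[k]] <- user[[k]]
  }
  cfg
}

validateConfig <- function(cfg) {
  if (is.null(cfg$out_dir)) stop("config: out_dir is required")
  if (is.null(cfg$plot_size_px) || cfg$plot_size_px < 1)
    stop("config: plot_size_px (community side length) is required")
  if (!is.null(cfg$n_components) && !is.null(cfg$variance_target))
    stop("config: n_components and variance_target are mutually exclusive")
  if (cfg$ndvi_threshold < -1 || cfg$ndvi_threshold > 1)
    stop("config: ndvi_threshold must lie in [-1, 1]")
  cfg
}

#' Run the full spectral-diversity workflow
#'
#' Chains preprocessing (band trimming, Savitzky-Golay smoothing, NDVI
#' masking, optional shade masking, brightness normalization), PCA feature
#' extraction, community tiling and the alpha/beta/gamma partition, writing
#' result tables, maps and a provenance log to `out_dir`. When masking
#' leaves unequal valid-pixel counts per community the rarefied partition is
#' used automatically; otherwise the exact partition runs once.
#'
#' Deterministic given the config and seed; rerunning yields byte-identical
#' tables. On failure, files already written by the failing run are removed
#' and the error is re-raised with its stage name.
#'
#' @param config a named list (merged over [defaultConfig()]), or the path
#'   to a YAML file of the same shape.
#' @param cube optionally, an in-memory [SpectralCube] (instead of
#'   `config$input`, an ENVI path).
#' @return (invisibly) a list with the preprocessed `cube`, the feature
#'   matrix `Y`, the `grid`, `pca` model, and `result` (a
#'   [SpectralPartition] or [RarefactionResult]).
#' @export
runPipeline <- function(config, cube = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  cfg <- validateConfig(mergeConfig(config))
  outDir <- cfg$out_dir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  note <- function(f) { written <<- c(written, f); f }
  logLines <- character()
  logMsg <- function(...) {
    logLines <<- c(logLines, sprintf(...))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      for (f in written) unlink(f)
      stop(sprintf("stage '%s': %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }

  cube <- stage("read", {
    if (is.null(cube)) {
      if (is.null(cfg$input)) stop("no input cube (config$input) given")
      readENVI(cfg$input)
    } else cube
  })
  logMsg("input: %d x %d pixels, %d bands, %d valid",
         dim(cube)[1], dim(cube)[2], dim(cube)[3], sum(validMask(cube)))

  cube <- stage("trim_bands", trimBands(cube, cfg$drop_windows,
                                        as.numeric(cfg$keep_range)))
  logMsg("trim_bands: %d bands retained", dim(cube)[3])
  cube <- stage("savgol", savgolSmooth(cube, cfg$sg_order, cfg$sg_window))
  cube <- stage("ndvi_mask",
                maskVegetation(cube, threshold = cfg$ndvi_threshold,
                               redWl = cfg$red_wl, nirWl = cfg$nir_wl))
  logMsg("ndvi_mask (< %.2f): %d valid pixels remain",
         cfg$ndvi_threshold, sum(validMask(cube)))
  if (isTRUE(cfg$shade_mask$enabled)) {
    cube <- stage("shade_mask",
                  shadeMask(cube, nirWl = cfg$nir_wl,
                            quantile = cfg$shade_mask$quantile))
    logMsg("shade_mask (q = %.2f): %d valid pixels remain",
           cfg$shade_mask$quantile, sum(validMask(cube)))
  }
  cube <- stage("brightness_normalize", brightnessNormalize(cube))

  Y <- stage("features", cubeToFeatures(cube))
  pca <- stage("pca", fitPCA(Y))
  scores <- stage("pca", transformPCA(pca, Y,
                                      nComponents = cfg$n_components,
                                      varianceTarget = cfg$variance_target))
  logMsg("pca: %d of %d components retained (%.1f%% of variance)",
         nFeatures(scores), nFeatures(Y),
         100 * sum(pca@relativeEigenvalues[seq_len(nFeatures(scores))]))

  d <- dim(cube)
  grid <- stage("community_grid",
                makeCommunityGrid(scores, cfg$plot_size_px, d[1:2]))
  counts <- communityCounts(grid)
  nEdge <- sum(is.na(communityAssignment(grid)))
  logMsg("community_grid: %d plots of %d x %d px; %d edge/unassigned pixels discarded",
         nCommunities(grid), cfg$plot_size_px, cfg$plot_size_px, nEdge)
  logMsg("valid pixels per plot: min %d, max %d (m_min = %d)",
         min(counts), max(counts), min(counts))

  equal <- length(unique(counts)) == 1L
  result <- stage("partition", {
    if (equal) {
      if (nEdge > 0L) {
        keep <- !is.na(communityAssignment(grid))
        sub <- featureMatrix(featureValues(scores)[keep, , drop = FALSE],
                             pixelCoords(scores)[keep, , drop = FALSE])
        subgrid <- grid
        subgrid@assignment <- grid@assignment[keep]
        partitionDiversity(Y = sub, grid = subgrid)
      } else partitionDiversity(Y = scores, grid = grid)
    }
    else rarefiedPartition(scores, grid,
                           repeats = cfg$rarefaction$repeats,
                           seed = cfg$seed,
                           aggregation = cfg$rarefaction$aggregation,
                           minFraction = cfg$rarefaction$min_fraction)
  })
  part <- if (is(result, "RarefactionResult")) result@aggregate else result
  if (is(result, "RarefactionResult"))
    logMsg("rarefied partition: %d repeats of m_min = %d", result@repeats,
           result@mMin)
  else logMsg("exact partition: equal m = %d", part@m)

  stage("write", {
    s <- summary(part)
    s[-1L] <- lapply(s[-1L], signif, digits = 4L)
    utils::write.csv(s, note(file.path(outDir, "summary.csv")),
                     row.names = FALSE)
    feat <- data.frame(feature = paste0("PC", seq_len(part@p)),
                       fcsd_gamma = fmt17(part@fcsdGamma),
                       fcsd_beta = fmt17(part@fcsdBeta))
    utils::write.csv(feat, note(file.path(outDir, "fcsd.csv")),
                     row.names = FALSE)
    commLab <- if (!is.null(names(part@lcsdBeta)))
      as.integer(names(part@lcsdBeta)) else seq_len(part@q)
    fa <- data.frame(community = rep(commLab, times = part@p),
                     feature = rep(paste0("PC", seq_len(part@p)),
                                   each = part@q),
                     fcsd_alpha = fmt17(as.vector(part@fcsdAlpha)))
    utils::write.csv(fa, note(file.path(outDir, "fcsd_alpha.csv")),
                     row.names = FALSE)
    utils::write.csv(
      data.frame(community = commLab,
                 lcsd_beta = fmt17(part@lcsdBeta)),
      note(file.path(outDir, "lcsd_beta.csv")), row.names = FALSE)
    utils::write.csv(
      data.frame(community = commLab,
                 sd_alpha = fmt17(part@sdAlphaK)),
      note(file.path(outDir, "sd_alpha.csv")), row.names = FALSE)
    lg <- part@lcsdGamma
    if (length(lg) != nPixels(scores)) {
      full <- rep(NA_real_, nPixels(scores))
      full[!is.na(communityAssignment(grid))] <- lg
      lg <- full
    }
    coords <- pixelCoords(scores)
    utils::write.csv(
      data.frame(row = coords[, 1L], col = coords[, 2L],
                 lcsd_gamma = fmt17(lg[seq_len(nrow(coords))])),
      note(file.path(outDir, "lcsd_gamma.csv")), row.names = FALSE)

    writeMapTIFF(communityMap(part@lcsdBeta, grid, d[1:2]),
                 note(file.path(outDir, "lcsd_beta.tif")))
    writeMapTIFF(communityMap(part@sdAlphaK, grid, d[1:2]),
                 note(file.path(outDir, "sd_alpha.tif")))
    lmap <- matrix(NA_real_, d[1L], d[2L])
    lmap[coords + 1L] <- lg[seq_len(nrow(coords))]
    writeMapTIFF(lmap, note(file.path(outDir, "lcsd_gamma.tif")))

    yaml::write_yaml(cfg, note(file.path(outDir, "config.yaml")))
    writeLines(logLines, note(file.path(outDir, "log.txt")))
  })

  invisible(list(cube = cube, Y = scores, grid = grid, pca = pca,
                 result = result, files = written))
}

# Fill each community's full plot rectangle with its per-community value;
# NA elsewhere. Values may cover a subset of communities (named by original
# label, as rarefaction with a floor produces).
communityMap <- function(values, grid, imageShape) {
  map <- matrix(NA_real_, imageShape[1L], imageShape[2L])
  if (is.na(grid@plotSizePx)) return(map)
  ps <- grid@plotSizePx
  nTileC <- (imageShape[2L] - grid@origin[2L]) %/% ps
  v <- rep(NA_real_, nCommunities(grid))
  idx <- if (!is.null(names(values))) as.integer(names(values))
         else seq_along(values)
  v[idx] <- values
  for (k in seq_len(nCommunities(grid))) {
    if (is.na(v[k])) next
    tr <- (k - 1L) %/% nTileC
    tc <- (k - 1L) %% nTileC
    rr <- grid@origin[1L] + tr * ps + seq_len(ps)
    cc <- grid@origin[2L] + tc * ps + seq_len(ps)
    map[rr, cc] <- v[k]
  }
  map
}
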