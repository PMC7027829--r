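#' Construct a SpectralCube
#'
#' Wraps a reflectance array, wavelength vector and optional mask into a
#' validated [SpectralCube]. Pixels containing non-finite reflectance in any
#' band are removed from the valid mask.
#'
#' @param reflectance numeric array, `rows x cols x bands`.
#' @param wavelengths numeric vector of band-center wavelengths in nm,
#'   strictly increasing, one per band. A `rows x cols` matrix is promoted to
#'   a single-band cube.
#' @param validMask logical `rows x cols` matrix; defaults to all `TRUE`.
#' @param geotransform optional length-6 affine geotransform.
#' @param nodata optional sentinel value; matching pixels are masked.
#' @return a [SpectralCube]
#' @examples
#' cube <- spectralCube(array(0.5, c(4, 4, 3)), c(500, 600, 700))
#' dim(reflectance(cube))
#' @export
spectralCube <- function(reflectance, wavelengths,
                         validMask = NULL, geotransform = numeric(),
                         nodata = numeric()) {
  if (length(dim(reflectance)) == 2L)
    dim(reflectance) <- c(dim(reflectance), 1L)
  d <- dim(reflectance)
  if (is.null(validMask))
    validMask <- matrix(TRUE, d[1L], d[2L])
  if (length(nodata) == 1L)
    reflectance[reflectance == nodata] <- NA_real_
  bad <- apply(is.na(reflectance) | !is.finite(reflectance), c(1L, 2L), any)
  validMask <- validMask & !bad
  new("SpectralCube",
      reflectance = reflectance,
      wavelengths = as.numeric(wavelengths),
      validMask = validMask,
      geotransform = as.numeric(geotransform),
      nodata = as.numeric(nodata))
}

#' @rdname SpectralCube-class
#' @aliases reflectance,SpectralCube-method
#' @export
setMethod("reflectance", "SpectralCube", function(x) x@reflectance)

#' @rdname SpectralCube-class
#' @aliases wavelengths,SpectralCube-method
#' @export
setMethod("wavelengths", "SpectralCube", function(x) x@wavelengths)

#' @rdname SpectralCube-class
#' @aliases validMask,SpectralCube-method
#' @export
setMethod("validMask", "SpectralCube", function(x) x@validMask)

#' @rdname SpectralCube-class
#' @aliases validMask<-,SpectralCube-method
#' @export
setMethod("validMask<-", "SpectralCube", function(x, value) {
  stopifnot(identical(dim(value), dim(x@validMask)))
  x@validMask <- x@validMask & value
  validObject(x)
  x
})

#' @rdname SpectralCube-class
#' @aliases geotransform,SpectralCube-method
#' @export
setMethod("geotransform", "SpectralCube", function(x) x@geotransform)

#' @rdname SpectralCube-class
#' @export
setMethod("dim", "SpectralCube", function(x) dim(x@reflectance))

setMethod("show", "SpectralCube", function(object) {
  d <- dim(object@reflectance)
  wl <- object@wavelengths
  cat(sprintf("SpectralCube: %d x %d pixels, %d bands (%.0f-%.0f nm)\n",
              d[1L], d[2L], d[3L], min(wl), max(wl)))
  cat(sprintf("  valid pixels: %d / %d\n",
              sum(object@validMask), d[1L] * d[2L]))
  if (length(object@geotransform) == 6L)
    cat("  georeferenced (affine geotransform present)\n")
})

#' Extract the pixel-by-feature matrix of valid pixels
#'
#' Flattens the valid pixels of a cube into a [FeatureMatrix] whose columns
#' are the reflectance bands (labelled by wavelength). Pixels are taken in
#' row-major image order.
#'
#' @param cube a [SpectralCube]
#' @return a [FeatureMatrix]
#' @export
cubeToFeatures <- function(cube) {
  if (sum(validMask(cube)) < 2L)
    stop("no valid pixels: fewer than 2 usable pixels remain in the cube")
  fm <- cubeAsMatrix(reflectance(cube), validMask(cube))
  colnames(fm$values) <- sprintf("%gnm", wavelengths(cube))
  featureMatrix(fm$values, fm$coords)
}

#' Construct a FeatureMatrix
#'
#' @param values numeric `n x p` matrix of pixels by spectral features.
#' @param pixelIndex `n x 2` matrix of 0-based (row, col) image coordinates;
#'   defaults to a single synthetic image column when the pixels have no
#'   spatial context.
#' @return a [FeatureMatrix]
#' @examples
#' Y <- featureMatrix(matrix(c(0, 0, 2, 2), ncol = 1))
#' nPixels(Y)
#' @export
featureMatrix <- function(values, pixelIndex = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(pixelIndex))
    pixelIndex <- cbind(row = seq_len(nrow(values)) - 1L, col = 0L)
  pixelIndex <- as.matrix(pixelIndex)
  storage.mode(pixelIndex) <- "integer"
  new("FeatureMatrix", values = values, pixelIndex = pixelIndex)
}

#' @rdname FeatureMatrix-class
#' @aliases featureValues,FeatureMatrix-method
#' @export
setMethod("featureValues", "FeatureMatrix", function(x) x@values)

#' @rdname FeatureMatrix-class
#' @aliases pixelCoords,FeatureMatrix-method
#' @export
setMethod("pixelCoords", "FeatureMatrix", function(x) x@pixelIndex)

#' @rdname FeatureMatrix-class
#' @aliases featureLabels,FeatureMatrix-method
#' @export
setMethod("featureLabels", "FeatureMatrix", function(x) colnames(x@values))

#' @rdname FeatureMatrix-class
#' @aliases nPixels,FeatureMatrix-method
#' @export
setMethod("nPixels", "FeatureMatrix", function(x) nrow(x@values))

#' @rdname FeatureMatrix-class
#' @aliases nFeatures,FeatureMatrix-method
#' @export
setMethod("nFeatures", "FeatureMatrix", function(x) ncol(x@values))

setMethod("show", "FeatureMatrix", function(object) {
  cat(sprintf("FeatureMatrix: %d pixels x %d features\n",
              nrow(object@values), ncol(object@values)))
  lab <- colnames(object@values)
  if (!is.null(lab))
    cat("  features:", paste(utils::head(lab, 6), collapse = ", "),
        if (length(lab) > 6) "...", "\n")
})
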