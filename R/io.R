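# Delimited-table and map IO. Machine tables use 17 significant digits so
# values round-trip exactly; the human summary is rounded to 4 significant
# digits. Maps are written as CSV (exact values) plus plain single-band
# TIFF rescaled to [0, 1] for quick visualization (the value range goes in
# the CSV).

fmt17 <- function(x) sprintf("%.17g", x)

#' Read a pixel-by-feature table
#'
#' Reads a delimited file with header `row,col,community,f1..fp` into a
#' [FeatureMatrix] and [CommunityGrid]. Ragged rows, non-numeric feature
#' values and duplicate (row, col) coordinates are rejected with the
#' offending line number.
#'
#' @param path path to the delimited file.
#' @param sep field separator (default `,`).
#' @return list with `Y` (a [FeatureMatrix]) and `grid` (a [CommunityGrid];
#'   community `NA` rows stay unassigned).
#' @seealso [writeFeatureTable()]
#' @export
readFeatureTable <- function(path, sep = ",") {
  if (!file.exists(path)) stop("file not found: ", path)
  nf <- utils::count.fields(path, sep = sep)
  if (!length(nf)) stop("empty file: ", path)
  if (length(unique(nf)) > 1L)
    stop(sprintf("ragged row at line %d of %s: %d fields where %d expected",
                 which(nf != nf[1L])[1L], path, nf[nf != nf[1L]][1L], nf[1L]))
  df <- utils::read.csv(path, sep = sep, check.names = FALSE,
                        colClasses = "character")
  need <- c("row", "col", "community")
  if (!all(need %in% names(df)[1:3]))
    stop("header must start with: row,col,community")
  if (ncol(df) < 4L) stop("no feature columns found")
  if (nrow(df) < 2L) stop("need at least 2 pixel rows")

  toNum <- function(col, name) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !(df[[col]] %in% c("NA", "")))
    if (length(bad))
      stop(sprintf("non-numeric value '%s' in column '%s' at line %d",
                   df[[col]][bad[1L]], name, bad[1L] + 1L))
    v
  }
  coords <- cbind(row = toNum("row", "row"), col = toNum("col", "col"))
  if (anyNA(coords)) stop("missing pixel coordinates")
  dup <- anyDuplicated(coords)
  if (dup)
    stop(sprintf("duplicate pixel coordinate (%g, %g) at line %d",
                 coords[dup, 1L], coords[dup, 2L], dup + 1L))
  comm <- suppressWarnings(as.integer(df[["community"]]))
  featCols <- names(df)[-(1:3)]
  vals <- vapply(featCols, function(cn) toNum(cn, cn),
                 numeric(nrow(df)))
  vals <- matrix(vals, nrow = nrow(df),
                 dimnames = list(NULL, featCols))
  list(Y = featureMatrix(vals, coords), grid = communityGrid(comm))
}

#' Write a pixel-by-feature table
#'
#' Inverse of [readFeatureTable()]: writes `row,col,community,f1..fp` with
#' 17 significant digits so a read-back reproduces the values exactly.
#'
#' @param Y a [FeatureMatrix]
#' @param grid a [CommunityGrid] aligned with `Y` (or `NULL` for all-`NA`
#'   community labels).
#' @param path output path.
#' @return the path, invisibly
#' @export
writeFeatureTable <- function(Y, grid, path) {
  comm <- if (is.null(grid)) rep(NA_integer_, nPixels(Y))
          else communityAssignment(grid)
  vals <- featureValues(Y)
  lab <- colnames(vals)
  if (is.null(lab)) lab <- paste0("f", seq_len(ncol(vals)))
  hdr <- paste(c("row", "col", "community", lab), collapse = ",")
  body <- apply(cbind(pixelCoords(Y), comm), 1L, paste, collapse = ",")
  feat <- apply(vals, 1L, function(r) paste(fmt17(r), collapse = ","))
  writeLines(c(hdr, paste(body, feat, sep = ",")), path)
  invisible(path)
}

# Write a numeric matrix as a greyscale 32-bit TIFF, linearly rescaled to
# [0, 1]; NA renders as 0. Returns the (min, max) used for the rescale.
writeMapTIFF <- function(values, path) {
  rng <- range(values, na.rm = TRUE)
  img <- if (diff(rng) > 0) (values - rng[1L]) / diff(rng)
         else values * 0
  img[is.na(img)] <- 0
  tiff::writeTIFF(img, path, bits.per.sample = 32L)
  invisible(rng)
}
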