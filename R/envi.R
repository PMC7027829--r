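# Minimal ENVI image IO. ENVI stores a flat binary data file next to a
# plain-text header (.hdr) giving dimensions, interleave, data type and,
# for spectroscopy products, per-band wavelengths. Only the floating-point
# data types (4 = float32, 5 = float64) and the three standard interleaves
# are supported; that covers reflectance products.

parseEnviHeader <- function(hdrPath) {
  txt <- readLines(hdrPath, warn = FALSE)
  if (!length(txt) || !grepl("^ENVI", txt[1L]))
    stop("not an ENVI header: ", hdrPath)
  body <- paste(txt[-1L], collapse = "\n")
  # join brace-delimited values onto one line
  body <- gsub("\\{([^}]*)\\}", "{\\1}", body)
  fields <- list()
  # split on newlines that are not inside braces
  depth <- 0L; cur <- ""; lines <- character()
  for (ch in strsplit(body, "")[[1L]]) {
    if (ch == "{") depth <- depth + 1L
    if (ch == "}") depth <- depth - 1L
    if (ch == "\n" && depth == 0L) { lines <- c(lines, cur); cur <- "" }
    else cur <- paste0(cur, ch)
  }
  lines <- c(lines, cur)
  for (ln in lines) {
    if (!grepl("=", ln)) next
    key <- tolower(trimws(sub("=.*$", "", ln)))
    val <- trimws(sub("^[^=]*=", "", ln))
    val <- gsub("[{}]", "", val)
    fields[[key]] <- trimws(val)
  }
  fields
}

#' Read an ENVI reflectance cube
#'
#' Reads a `.hdr`/data-file pair (BSQ, BIL or BIP interleave; float32 or
#' float64 samples) into a [SpectralCube]. Wavelengths are taken from the
#' header `wavelength` field; a `data ignore value` is applied as the nodata
#' sentinel so flagged pixels enter the cube masked. A nonstandard
#' `geotransform` header key (six comma-separated numbers), as written by
#' [writeENVI()], is restored when present.
#'
#' @param path path to the `.hdr` file or to the data file beside it.
#' @return a [SpectralCube]
#' @seealso [writeENVI()]
#' @export
readENVI <- function(path) {
  hdr <- if (grepl("\\.hdr$", path)) path else paste0(path, ".hdr")
  if (!file.exists(hdr)) hdr <- sub("\\.[^.]+$", ".hdr", path)
  if (!file.exists(hdr)) stop("ENVI header not found for: ", path)
  dat <- sub("\\.hdr$", "", hdr)
  for (ext in c("", ".dat", ".img", ".bsq")) {
    if (file.exists(paste0(dat, ext))) { dat <- paste0(dat, ext); break }
  }
  if (!file.exists(dat)) stop("ENVI data file not found for: ", hdr)

  h <- parseEnviHeader(hdr)
  need <- c("samples", "lines", "bands", "data type", "interleave")
  miss <- setdiff(need, names(h))
  if (length(miss))
    stop("ENVI header missing field(s): ", paste(miss, collapse = ", "))
  samples <- as.integer(h[["samples"]])
  lines   <- as.integer(h[["lines"]])
  bands   <- as.integer(h[["bands"]])
  dtype   <- as.integer(h[["data type"]])
  il      <- tolower(h[["interleave"]])
  offset  <- if (!is.null(h[["header offset"]]))
    as.integer(h[["header offset"]]) else 0L
  endian <- if (!is.null(h[["byte order"]]) &&
                as.integer(h[["byte order"]]) == 1L) "big" else "little"
  size <- switch(as.character(dtype), "4" = 4L, "5" = 8L,
                 stop("unsupported ENVI data type: ", dtype,
                      " (only float32/float64 supported)"))

  con <- file(dat, "rb")
  on.exit(close(con))
  if (offset > 0L) readBin(con, "raw", offset)
  v <- readBin(con, "double", n = samples * lines * bands,
               size = size, endian = endian)
  if (length(v) != samples * lines * bands)
    stop("ENVI data file shorter than header dimensions imply")
  refl <- switch(il,
    bsq = aperm(array(v, c(samples, lines, bands)), c(2L, 1L, 3L)),
    bil = aperm(array(v, c(samples, bands, lines)), c(3L, 1L, 2L)),
    bip = aperm(array(v, c(bands, samples, lines)), c(3L, 2L, 1L)),
    stop("unsupported interleave: ", il))

  wl <- if (!is.null(h[["wavelength"]]))
    as.numeric(strsplit(h[["wavelength"]], ",")[[1L]])
  else seq_len(bands)
  geo <- if (!is.null(h[["geotransform"]]))
    as.numeric(strsplit(h[["geotransform"]], ",")[[1L]]) else numeric()
  nodata <- if (!is.null(h[["data ignore value"]]))
    as.numeric(h[["data ignore value"]]) else numeric()
  spectralCube(refl, wl, geotransform = geo, nodata = nodata)
}

#' Write a SpectralCube as an ENVI image
#'
#' Writes a BSQ float32 (or float64) data file plus `.hdr` header carrying
#' the wavelengths, a `data ignore value`, and the geotransform. Invalid
#' pixels are written as the nodata value in every band, so the valid mask
#' survives a round trip through [readENVI()].
#'
#' @param cube a [SpectralCube]
#' @param path output path; `.hdr` is appended for the header, the data file
#'   gets extension `.dat`.
#' @param nodata sentinel written into masked pixels (default -9999).
#' @param doublePrecision write float64 instead of float32.
#' @return the data-file path, invisibly
#' @export
writeENVI <- function(cube, path, nodata = -9999, doublePrecision = FALSE) {
  path <- sub("\\.(hdr|dat)$", "", path)
  refl <- reflectance(cube)
  d <- dim(refl)
  bad <- !validMask(cube)
  if (any(bad)) {
    idx <- which(bad)
    for (b in seq_len(d[3L]))
      refl[idx + (b - 1L) * d[1L] * d[2L]] <- nodata
  }
  refl[is.na(refl)] <- nodata
  v <- as.vector(aperm(refl, c(2L, 1L, 3L)))   # sample-fastest, BSQ
  dat <- paste0(path, ".dat")
  con <- file(dat, "wb")
  writeBin(v, con, size = if (doublePrecision) 8L else 4L,
           endian = "little")
  close(con)
  hdr <- c(
    "ENVI",
    "description = {specvar export}",
    paste0("samples = ", d[2L]),
    paste0("lines = ", d[1L]),
    paste0("bands = ", d[3L]),
    "header offset = 0",
    "file type = ENVI Standard",
    paste0("data type = ", if (doublePrecision) 5L else 4L),
    "interleave = bsq",
    "byte order = 0",
    paste0("data ignore value = ", format(nodata)),
    "wavelength units = Nanometers",
    paste0("wavelength = {", paste(format(wavelengths(cube), trim = TRUE),
                                   collapse = ", "), "}"))
  if (length(geotransform(cube)) == 6L)
    hdr <- c(hdr, paste0("geotransform = {",
                         paste(format(geotransform(cube), trim = TRUE),
                               collapse = ", "), "}"))
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(dat)
}
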