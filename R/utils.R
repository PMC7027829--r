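# Internal helpers shared across modules.

# Index of the band whose center wavelength is nearest to `wl`.
# Ties resolve to the lower-wavelength band (which.min convention).
nearestBand <- function(wavelengths, wl) {
  which.min(abs(wavelengths - wl))
}

# Deterministic substream seed for repeat r, community k of a rarefaction run.
# Counter scheme keeps draws independent of community iteration order and of
# how many communities precede k; values stay inside 32-bit integer range.
substreamSeed <- function(master, r, k) {
  s <- (as.double(master) + 100003 * as.double(r) + 1009 * as.double(k)) %%
    2147483647
  as.integer(if (s == 0) 1 else s)
}

# Relative difference guarded against a zero reference.
relDiff <- function(x, ref) {
  d <- abs(x - ref)
  if (max(abs(ref)) == 0) d else d / max(abs(ref))
}

# Contribution index with an undefined (NA) result when the denominator is 0.
safeShare <- function(num, den) {
  if (den <= 0) rep(NA_real_, length(num)) else num / den
}

# Split band indices into contiguous wavelength segments: a new segment
# starts wherever the spacing exceeds gapFactor times the median spacing
# (the gaps left by water-band removal are an order of magnitude wider than
# the native band spacing).
wavelengthSegments <- function(wavelengths, gapFactor = 2.5) {
  b <- length(wavelengths)
  if (b <= 1L) return(list(seq_len(b)))
  dw <- diff(wavelengths)
  thr <- gapFactor * stats::median(dw)
  breaks <- which(dw > thr)
  starts <- c(1L, breaks + 1L)
  ends <- c(breaks, b)
  Map(seq.int, starts, ends)
}

# rows x cols x bands array -> (pixels x bands) matrix in row-major pixel
# order, restricted to `keep` (logical matrix). Returns the matrix and the
# 0-based (row, col) coordinates of the kept pixels.
cubeAsMatrix <- function(refl, keep) {
  d <- dim(refl)
  idx <- which(t(keep))                      # row-major order over pixels
  cols0 <- (idx - 1L) %% d[2L]
  rows0 <- (idx - 1L) %/% d[2L]
  flat <- matrix(refl, nrow = d[1L] * d[2L], ncol = d[3L])
  lin <- rows0 + 1L + cols0 * d[1L]          # column-major linear index
  list(values = flat[lin, , drop = FALSE],
       coords = cbind(row = rows0, col = cols0))
}
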