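# Fixtures and independent oracles used across the suite.

# Random pixel-by-feature matrix.
randomY <- function(n, p, seed = 1) {
  set.seed(seed)
  matrix(rnorm(n * p), n, p)
}

# Equal-m grid of q communities over n = q * m pixels.
equalGrid <- function(q, m) {
  communityGrid(rep(seq_len(q), each = m))
}

# Independent oracle for the total sum of squares: mean over pixels of the
# summed squared pairwise Euclidean distances, SS = (1/n) * sum_{i<i'} d^2.
ssPairwiseOracle <- function(Y) {
  sum(dist(Y)^2) / nrow(Y)
}

# Independent oracle for the among/within split: per-feature one-way ANOVA
# (stats::aov), component sums of squares added over features.
ssAnovaOracle <- function(Y, k) {
  f <- factor(k)
  between <- 0; within <- 0
  for (j in seq_len(ncol(Y))) {
    tab <- summary(stats::aov(Y[, j] ~ f))[[1L]]
    between <- between + tab["f", "Sum Sq"]
    within <- within + tab["Residuals", "Sum Sq"]
  }
  list(between = between, within = within)
}

# Small cube whose spectra are a deterministic function of pixel position,
# on a uniform wavelength grid.
makeTestCube <- function(rows = 4, cols = 4, wl = seq(400, 700, by = 10),
                         fun = function(r, c, w) 0.2 + 0.001 * (r + c) + 0 * w) {
  refl <- array(0, c(rows, cols, length(wl)))
  for (r in seq_len(rows))
    for (cc in seq_len(cols))
      refl[r, cc, ] <- fun(r, cc, wl)
  spectralCube(refl, wl)
}
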