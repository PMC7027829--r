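---
title: "Partitioning spectral diversity into alpha and beta components"
author: "specvar"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning spectral diversity into alpha and beta components}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specvar)
```

## The model

`specvar` measures the spectral diversity of a vegetated region as the
*spectral variance* of its pixels. Let $\mathbf{Y} = [y_{ij}]$ be the matrix
holding the positions of $n$ pixels (rows $i$) along $p$ spectral features
(columns $j$) — reflectance bands, principal-component scores, or
user-supplied vegetation indices. With $\bar{y}_j$ the column means, the
squared deviations $s_{ij} = (y_{ij} - \bar{y}_j)^2$ sum to the total sum
of squares of the region,

$$\mathrm{SS}_\gamma = \sum_{i=1}^{n}\sum_{j=1}^{p} s_{ij}, \qquad
  \mathrm{SD}_\gamma = \mathrm{SS}_\gamma / (n - 1),$$

and $\mathrm{SD}_\gamma$ — the total variance of $\mathbf{Y}$ — is the
region's spectral $\gamma$-diversity. Because it is a variance, it is
comparable across regions with different pixel counts; the raw
$\mathrm{SS}_\gamma$ statistics of adjacent regions can be pooled
(`mergeRegions()`), their $\mathrm{SD}_\gamma$ values cannot.

Splitting the region into $q$ communities (square tiles standing in for
vegetation inventory plots) of $m$ pixels each, the classical one-way
decomposition of the sum of squares partitions $\mathrm{SS}_\gamma$
additively:

$$\mathrm{SS}_\gamma = \mathrm{SS}_\beta + \mathrm{SS}_\alpha,$$

where $\mathrm{SS}_\beta = \sum_k \sum_j m\,(\hat{y}_{kj} - \bar{y}_j)^2$
measures variation *among* community centroids $\hat{y}_{kj}$ and
$\mathrm{SS}_\alpha = \sum_k \sum_j \sum_i (y_{ijk} - \hat{y}_{kj})^2$
variation *within* communities. Spectral $\beta$-diversity is
$\mathrm{SD}_\beta = \mathrm{SS}_\beta/(n-1)$ (a non-directional measure of
compositional heterogeneity among communities), and each community has its
own spectral $\alpha$-diversity
$\mathrm{SD}_{\alpha,k} = \mathrm{SS}_{\alpha,k}/(m-1)$.

Every sum of squares decomposes further into interpretable shares:

* **LCSD** (local contributions): a pixel's share of $\mathrm{SS}_\gamma$
  (its squared distance to the region centroid, normalized) or a
  community's share of $\mathrm{SS}_\beta$ (how spectrally distinct it is
  from the average community). Each set sums to 1 and can be mapped.
* **FCSD** (feature contributions): a feature's share of
  $\mathrm{SS}_\gamma$, $\mathrm{SS}_\beta$, or of one community's
  $\mathrm{SS}_{\alpha,k}$. When the features are full-rank PCA scores with
  type-1 (distance-preserving) scaling, the $\gamma$ feature contributions
  are exactly the relative eigenvalues.

Shares with a zero denominator (e.g. $\mathrm{LCSD}_\beta$ when
$\mathrm{SS}_\beta = 0$) are reported as `NA` ("undefined"), never as 0/0.

### Assumptions

* The partition identity assumes **equal $m$ across communities**. With
  unequal valid-pixel counts (the normal case after masking), the package
  enforces the identity by rarefaction (below) rather than by reweighting.
* Distances in feature space are **Euclidean**. Brightness normalization
  and (optional) PCA change what "distance" means ecologically; the
  partition itself is agnostic.
* Pixels should be at most about the size of an individual canopy plant,
  so that pixel-level variance tracks plant-level differences.

## The workflow

`runPipeline()` chains the steps a practitioner would apply to an airborne
reflectance cube. Tunable parameters, defaults, and the reasoning:

| parameter | default | units | rationale |
|---|---|---|---|
| `drop_windows` | 1340–1455, 1790–1955 | nm | atmospheric water-vapour bands with unusable signal |
| `keep_range` | 400–2400 | nm | trims noisy spectrum ends |
| `sg_order`, `sg_window` | 3, 7 | –, bands | Savitzky–Golay smoothing strong enough to kill single-band noise while preserving absorption-feature shape |
| `ndvi_threshold` | 0.8 | – | retains dense green vegetation only; pixels *equal* to the threshold are kept (the mask rule is strictly "below") |
| `red_wl`, `nir_wl` | 670, 800 | nm | standard broadband NDVI bands; snapped to the nearest available band center and overridable because sensors differ |
| `shade_mask` | off, quantile 0.2 | – | coarse NIR-quantile shadow filter; off by default because shadow removal changes diversity estimates little in closed canopies |
| `n_components` / `variance_target` | all / – | – | PC retention is a scene-specific judgement; an explicit count (or a cumulative-variance rule) replaces visual inspection, which cannot be automated faithfully |
| `plot_size_px` | required | px | the community (sampling-unit) size; e.g. 40 px at 1 m ≈ a 40 × 40 m forest inventory plot |
| `rarefaction$repeats` | 30 | – | enough repeats for stable means at the 90%+ retention rates typical after NDVI masking |
| `rarefaction$aggregation` | mean | – | median available for skewed distributions |
| `rarefaction$min_fraction` | none | – | optional floor to drop sparsely vegetated plots before `m_min` is computed |

Preprocessing order matters: bands are trimmed first, so smoothing must not
bridge the resulting spectral gaps — the filter runs independently within
each contiguous wavelength segment. Brightness normalization (each valid
spectrum divided by its L2 norm) comes last, removing per-pixel
illumination scaling so that subsequent variance reflects spectral *shape*.

PCA is covariance PCA (divisor $n-1$) on the normalized spectra, fit once
on all valid pixels; rarefaction subsamples the resulting scores rather
than refitting per repeat. Fitting once keeps the feature space — and
therefore all FCSD interpretations — fixed across repeats, at the cost of a
slight dependence of the loadings on communities' unequal footprints.

## Numerical choices

* Deviations are computed against explicitly materialized column means
  (two passes), not via $E[x^2]-E[x]^2$; the additivity identity then holds
  to near machine precision, and `partitionDiversity()` *asserts* it at a
  relative tolerance of $10^{-9}$ rather than silently returning an
  inconsistent bundle.
* **Savitzky–Golay edges**: each segment's edge samples are smoothed with
  the standard least-squares edge polynomials rather than by mirror
  padding. This keeps the filter's defining property — polynomials of
  degree $\le$ order are reproduced exactly at *every* sample, edges
  included (mirror padding breaks it at segment boundaries) — and keeps
  output length equal to input length.
* Segment detection: a gap is declared where the band spacing exceeds 2.5
  times the median spacing (`gapFactor`); the water-band gaps are an order
  of magnitude wider than any native band spacing.
* PCA loading signs are fixed deterministically (largest-magnitude element
  of each column made positive, ties to the lowest feature index). Signs
  affect no SS/SD/LCSD/FCSD value; the convention exists purely so exported
  score maps are reproducible.
* Wavelength requests (NDVI, shade mask) snap to the nearest band center;
  ties resolve to the lower wavelength. Requests that snap to the same band
  raise a configuration error.
* Rarefaction randomness: community $k$ in repeat $r$ draws from substream
  seed $(\text{master} + 100003\,r + 1009\,k) \bmod (2^{31}-1)$, so draws
  are independent of community iteration order and bit-reproducible.
* Degenerate inputs (all pixels identical, single community, single-pixel
  communities, zero spectra among valid pixels) raise explicit errors or
  `NA` flags as documented on each function; masked pixels are never
  imputed.

## The synthetic-landscape simulator

`simulateScenarioPair()` reproduces a two-scenario experiment on a
25 × 25-pixel landscape tiled into 25 communities of 5 × 5 pixels,
populated from a library of 15 leaf spectra (3 species × 5 individuals,
`makeLeafSpectra()`):

* Species spectra are built from a visible continuum minus Gaussian
  pigment absorptions (445, 670 nm), a sigmoid red edge to a NIR plateau,
  Gaussian water absorptions (1450, 1940 nm) and a broad SWIR decline, on a
  400–2400 nm grid at 10 nm (201 bands). The three parameter sets emulate
  temperate broadleaf trees with clearly distinct NIR plateaus and water
  contents, so interspecific distances exceed intraspecific ones — the
  property the scenario contrast depends on.
* Individuals jitter the species parameters with Gaussian noise
  (`individualSd = 0.06`, clamped at ±2 SD so spectra stay physical and
  canopy NDVI stays above the 0.8 vegetation threshold).
* **High-β scenario**: one species per community, drawn with probabilities
  0.60/0.35/0.05 (a common, a frequent and a rare species); each pixel
  receives one of that species' individual spectra uniformly with
  replacement. Within-community variation is therefore intraspecific only.
* **Low-β scenario**: a uniform random permutation of the pixel positions
  of the high-β landscape. The multiset of spectra — hence
  $\mathrm{SS}_\gamma$, exactly, to the last bit — is preserved, while the
  among-community component collapses to its random-mixing expectation
  (about $(q-1)/(n-1) \approx 4\%$ of $\mathrm{SS}_\gamma$).

What the simulator does **not** emulate: varying illumination and viewing
geometry, shadows, mixed and non-vegetated pixels, sensor noise and
atmospheric residuals, spatial autocorrelation within communities, and
crown-scale structure. Passing tests on simulated landscapes therefore
validate the *mathematics and the workflow plumbing*, not the ecological
performance of spectral diversity on real imagery.

```{r scenario, eval = FALSE}
pair <- simulateScenarioPair(seed = 42)
f <- scenarioFeatures(pair$high)
partitionDiversity(f$Y, f$grid)
```

## Design decisions where the design was open

* **Merging regions**: adding regional $\mathrm{SS}_\gamma$ values and
  dividing by the pooled $n - 1$ is exact only when all regions' deviations
  are taken from the joint mean. `mergeRegions()` implements the simple
  additive rule and documents the caveat instead of silently re-centering.
* **Mean α-diversity**: under equal $m$, the mean of the per-community
  $\mathrm{SD}_{\alpha,k}$ equals $\mathrm{SS}_\alpha / (q\,(m-1))$; both
  are available (`meanAlphaSD()`, the `sdAlphaMean` slot) and tested equal.
* **Rarefaction floor**: no community is dropped by default; a
  `min_fraction` floor is available for sparsely vegetated plots whose tiny
  valid-pixel counts would otherwise drag `m_min` down for the whole scene.
* **Per-pixel LCSD under rarefaction** is averaged only over the repeats in
  which the pixel was drawn; pixels never drawn report `NA` rather than a
  diluted value.
* **Map output** is written as exact-value CSV plus plain single-band TIFF
  (linearly rescaled for display); georeferencing is carried in-memory and
  into ENVI headers, not into the TIFFs.

## Problem sizes

The shipped test-suite and the acceptance script exercise: hand-checkable
4–60-pixel matrices for every identity; 1,000 random landscape instances
for additivity; brute-force pairwise-distance cross-checks up to $n = 200$;
and the full 25 × 25 × 201-band scenario pair, including a 100-seed sweep
of the high-/low-β contrast. These sizes make the whole suite run in well
under a minute while covering every code path; the algorithms themselves
are vectorized and scale linearly in $n\,p$ (the forest-scene geometry,
175 plots × 1474 pixels, is exercised analytically through the scaling
identities).

## Known limitations

* No atmospheric correction, BRDF correction or orthorectification: input
  must already be surface reflectance.
* ENVI IO supports float32/float64 BSQ/BIL/BIP only; GeoTIFF input is not
  supported (supply a wavelength sidecar and convert to ENVI).
* The shade mask is a deliberately simple NIR-quantile filter, not a
  geometric shadow model.
* LCSD values come with no significance test; they are descriptive shares.
* `mergeRegions()` inherits the joint-centering caveat above.
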