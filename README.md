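# specvar — partitioning plant spectral diversity into α and β components

Imaging spectroscopy measures reflected solar radiation in hundreds of
narrow bands for every pixel of an aerial scene. Because plant species
differ in pigments, water content, and canopy structure, the *variation*
among pixel spectra — spectral diversity — integrates chemical, structural
and taxonomic diversity and can be mapped wall-to-wall where field
inventories cannot.

`specvar` is an R package for ecologists and remote-sensing scientists that
measures spectral diversity as **spectral variance** and partitions it the
way community ecology partitions species diversity. For a pixel × feature
matrix **Y** (*n* pixels, *p* spectral features) with column means ȳⱼ:

- **γ-diversity** of a region: SS_γ = Σᵢⱼ (y_ij − ȳⱼ)², SD_γ = SS_γ/(n−1)
  — the total variance of **Y**;
- tiling the region into *q* communities (square plots) of *m* pixels, the
  classical ANOVA identity splits it additively,
  **SS_γ = SS_β + SS_α**: among-community (**β**) and within-community
  (**α**) components, with SD_β = SS_β/(n−1) and per-community
  SD_α,k = SS_α,k/(m−1);
- **LCSD** indices give each pixel's share of SS_γ and each community's
  share of SS_β (mappable "spectral uniqueness"); **FCSD** indices give
  each feature's share of each component — equal to the relative
  eigenvalues for γ when the features are full-rank, type-1-scaled PCA
  scores.

Around that core the package provides the full workflow: ENVI cube IO,
water-band removal, Savitzky–Golay smoothing, NDVI and optional shade
masking, brightness (L2) normalization, distance-preserving PCA, square
community tiling, and a seeded rarefaction procedure for communities with
unequal vegetated-pixel counts — plus a synthetic hyperspectral landscape
simulator for method evaluation.

## Worked example

Simulate a landscape of 25 communities (5 × 5 pixels each) where each
community holds a single tree species, then run the full pipeline
(trim → smooth → NDVI mask → normalize → PCA → partition):

```r
library(specvar)

pair <- simulateScenarioPair(seed = 42)
res  <- runPipeline(list(plot_size_px = 5, n_components = 3, seed = 42,
                         out_dir = "demo_out"),
                    cube = pair$high@cube)
res$result
#> SpectralPartition: n = 625 pixels, p = 3 features, q = 25 communities of m = 25
#>   SS_gamma = 1.849 (SD_gamma = 0.002963)
#>   SS_beta  = 1.793 (97.0%; SD_beta = 0.002873)
#>   SS_alpha = 0.05585 (3.0%; mean SD_alpha = 9.308e-05)
```

Species-pure communities concentrate almost all spectral variance *among*
communities: β accounts for 97% of SS_γ. The most spectrally distinctive
plots are read off the community contributions:

```r
head(sort(lcsdBeta(res$result), decreasing = TRUE), 3)
#>         17         23          9
#> 0.06355642 0.06184402 0.04524964
```

Permuting the pixels to random positions (`pair$low`) leaves SS_γ exactly
unchanged — the same multiset of spectra — but collapses SS_β to ~4% and
moves the variance into the within-community component, reversing the β/α
balance at identical γ-diversity.

`demo_out/` contains `summary.csv`, feature-contribution tables
(`fcsd.csv`, `fcsd_alpha.csv`), per-plot `lcsd_beta.csv`/`sd_alpha.csv`,
per-pixel `lcsd_gamma.csv`, TIFF maps of each, and the provenance log and
config. A thin CLI over the same functions is installed at
`inst/scripts/specvar` (`specvar simulate | run | partition`).

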