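Package: specvar
Title: Partitioning Plant Spectral Diversity into Alpha and Beta Components
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Measures plant spectral diversity from imaging spectroscopy as
    spectral variance and partitions the total (gamma) variance of a region
    additively into among-community (beta) and within-community (alpha)
    components. Provides per-pixel and per-community local contributions
    (LCSD) and per-feature contributions (FCSD) to each component, the full
    preprocessing workflow for hyperspectral reflectance cubes (water-band
    removal, Savitzky-Golay smoothing, NDVI masking, brightness
    normalization), distance-preserving (type-1 scaled) principal component
    feature extraction, a rarefaction procedure for communities with unequal
    numbers of vegetated pixels, and a synthetic-landscape simulator for
    method evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    signal,
    yaml,
    tiff
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'utils.R'
    'cube.R'
    'envi.R'
    'preprocess.R'
    'features.R'
    'partition.R'
    'rarefaction.R'
    'simulate.R'
    'io.R'
    'pipeline.R'
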