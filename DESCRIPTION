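Package: emgrid
Title: Spatial Localization of Muscle Activity from High-Density Surface EMG Grids
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis of high-density surface electromyography (EMG) recorded
    with two-dimensional electrode grids. Provides electrode-grid geometry with
    masked cells, band-pass preprocessing with automatic bad-channel detection
    and neighbour interpolation, steadiest-force epoch selection, monopolar RMS
    amplitude maps, watershed segmentation of the equalized map, selection of
    the primary activity cluster, barycenter localization of the active region
    with anatomical normalization, and a factorial ANOVA layer with Holm-Sidak
    post-hoc tests for discriminating contraction tasks. Includes a synthetic
    multichannel EMG generator with known ground-truth source positions for
    validation studies.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    signal,
    jsonlite,
    withr,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    EBImage
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'grid.R'
    'recording.R'
    'simulate.R'
    'preprocess.R'
    'map.R'
    'localize.R'
    'stats.R'
    'pipeline.R'
    'emgrid-package.R'
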