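Package: icctransients
Title: Spatio-Temporal Quantification of Ca2+ Transients in Interstitial
    Cells of Cajal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for quantifying localized, stochastic Ca2+ transients in
    spindle-shaped interstitial cells of Cajal of the intestinal deep
    muscular plexus (ICC-DMP) imaged with genetically encoded indicators.
    Builds motion-stabilized, dF/F0-normalized spatio-temporal (ST) maps
    from single-channel fluorescence stacks and whole-cell ROIs, detects
    Ca2+ events and measures amplitude, full duration at half maximum,
    spatial spread and propagation velocity, clusters event initiation
    loci into firing sites, and analyses electrical field stimulation
    (EFS) epochs including per-site escape-from-inhibition latencies.
    Includes a calibrated synthetic-recording generator with ground-truth
    ledgers so every pipeline stage can be validated by parameter
    recovery, and the summary/comparison statistics conventions used in
    this field (mean +/- SEM, D'Agostino-Pearson normality screening,
    t-test/ANOVA with star coding).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    tiff,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'detect.R'
    'efs.R'
    'icctransients-package.R'
    'io.R'
    'measure.R'
    'pipeline.R'
    'presets.R'
    'sites.R'
    'stabilize.R'
    'stats.R'
    'utils.R'
    'stmap.R'
    'synthetic-cell.R'
    'synthetic-events.R'
    'synthetic-render.R'
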