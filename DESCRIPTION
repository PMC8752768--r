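Package: evomorph
Title: Morphometry and Evolutionary Dynamics of Bacterial Populations from
    Imaging Flow Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of rod-to-sphere morphological change during
    serial-transfer experimental evolution of Escherichia coli, as observed by
    imaging flow cytometry. Provides event-quality gating (fluorescence
    intensity, aspect-ratio intensity, gradient-RMS focus filtering),
    single-cell morphometry (major/minor axis lengths via spherocylinder model
    fitting, projected area, aspect ratio, spherocylinder volume, area-to-volume
    ratio, GFP-based protein abundance), growth-rate and carrying-capacity
    estimation, evolutionary-trajectory regression, fold-change statistics with
    exact permutation tests, and feature-correlation significance analysis. A
    synthetic-data generator simulates the serial-transfer evolution experiment
    and the flow cytometer's single-cell images with known ground truth, so
    every stage of the pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    minpack.lm,
    EBImage,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    tiff
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'capsule.R'
    'evodynamics.R'
    'evomorph-package.R'
    'gating.R'
    'growth.R'
    'io.R'
    'methods-accessors.R'
    'morphometry.R'
    'stats_report.R'
    'simulate.R'
    'pipeline.R'
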