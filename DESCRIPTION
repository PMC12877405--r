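Package: stretchquant
Title: Quantification of Fluorescence Readouts in Cell-Stretching Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Image-analysis pipelines for uniaxial cyclic cell-stretching
    assays on fluorescence microscopy data: actin stress-fiber orientation
    from gray-value gradients on a grid of cell equivalents, LC3B
    autophagosome puncta counting with distance-transform watershed
    splitting, two-channel paxillin/vinculin focal-adhesion colocalization
    and reorientation, mitochondrial morphology (Tomm20), MitoTracker
    intensity, and JC-1 red/green membrane-potential ratios. Includes a
    synthetic fluorescence-scene generator with ground truth for every
    assay, angular-distribution statistics (two-sample Kolmogorov-Smirnov,
    Mann-Whitney, bootstrap confidence bands), and a config-driven runner.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    png,
    signal,
    jsonlite,
    yaml,
    stats,
    utils,
    tools,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
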