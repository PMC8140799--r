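Package: sectionFISH
Title: Quantitative Copy Number Estimation from FISH of Tissue Sections
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimates absolute DNA copy number from fluorescence in situ
    hybridization (FISH) of thin tissue sections, where most nuclei are only
    partially captured by the section. Provides spherical-nucleus volume
    correction for observed spot counts, a Gamma-Poisson posterior model for
    manually counted nuclei, a homogeneous Poisson point-process model for
    automated counting that avoids single-nucleus segmentation, the standard
    control-probe baseline, a tissue-section simulator and benchmark, and a
    simplified spot-segmentation image pipeline with a synthetic field
    generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr,
    rmarkdown
biocViews: CopyNumberVariation, FISH, Bayesian, CellBiology, Visualization
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
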