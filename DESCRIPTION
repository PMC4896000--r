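Package: subpopdyn
Title: Subpopulation Dynamics of Transcription-Factor Activation from
    Imaging Flow Cytometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decomposes cell-to-cell heterogeneity in transcription-factor
    activation states measured by multispectral imaging flow cytometry.
    Provides mask-based single-cell feature extraction (nuclear,
    cytoplasmic and cellular compartments, nuclear/cytoplasmic intensity
    ratios, radial marker positioning), density-normalized downsampling
    followed by k-means agglomerative clustering into activity phenotypes,
    criteria-driven selection of the clustering feature set and cluster
    number, cross-treatment classification with a frozen model, and
    subpopulation time-course analysis. A synthetic-data generator
    emulating the mixture structure of TFEB activation phenotypes makes
    the full pipeline testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
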