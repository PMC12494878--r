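Package: AggloAssay
Title: Quantitative Assays Separating Protein Agglomerates from Aggregates
Version: 0.99.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools to classify fluorescent puncta-forming protein variants
    along an agglomerate-aggregate axis in budding yeast. Implements per-cell
    puncta detection from two-channel fluorescence images, a wild-type
    dissolution assay with ratio-quantile binning, an intersection-over-union
    co-localization score against chaperone markers, growth-curve and
    competition-based fitness estimation, an integrated circular-dichroism
    spectral divergence, and a resampling-based category over-representation
    test for label-free proteomics. A synthetic-data module generates every
    input with known ground truth so the whole pipeline is testable without
    microscopes, plate readers, chemostats, or mass spectrometers.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    tiff,
    yaml,
    limma,
    EBImage,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr
Config/testthat/edition: 3
biocViews: CellBiology, Proteomics, Software
RoxygenNote: 7.3.3
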