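Package: segraquant
Title: Quantification Pipelines for Covalent Selective Glucocorticoid
    Receptor Agonist Characterization
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipelines for the cell-biological and biochemical
    characterization of covalent selective glucocorticoid receptor (GR)
    agonists: per-cell nuclear-to-cytoplasm GR translocation scoring from
    two-channel fluorescence images (isodata thresholding, conditional
    watershed splitting of touching nuclei, Voronoi-restrained cytoplasmic
    ring ROIs), reporter-gene transactivation and transrepression
    statistics with a resampling many-to-one test, competition-binding
    four-parameter-logistic IC50 fitting and Cheng-Prusoff Ki conversion,
    coregulator peptide-array modulation-index profiling with Ward
    clustering, and in-silico tryptic digestion with covalent
    cysteine-adduct mass mapping. Every input can be simulated with known
    ground truth, so the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    minpack.lm,
    tiff,
    Biostrings,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pheatmap
Config/testthat/edition: 3
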