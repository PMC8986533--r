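Package: wgdqc
Title: Quantifying Genetic Instability in the First Cell Cycle After
    Whole-Genome Duplication
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis toolkit for measuring genetic instability arising in
    the first interphase after whole-genome duplication. Implements
    single-cell copy-number calling from binned read counts with two
    independent callers (penalized changepoint segmentation and a sticky
    hidden Markov model), library curation by dual-caller concordance,
    per-copy read-depth minimums and a wavy-pattern artifact filter built
    on non-rounded copy numbers, karyotype scoring (aneuploidy,
    heterogeneity, aneuploid genome fraction) with genome-wide heatmaps,
    DNA-combing fork analytics (fork speed, CldU/IdU asymmetry,
    inter-origin distance), and per-nucleus DNA-damage quantification
    (focus detection, coverage-times-intensity damage index,
    Manders/Costes colocalization). Includes seeded synthetic-data
    generators for all three input classes with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
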