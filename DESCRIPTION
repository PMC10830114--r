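Package: remethylome
Title: DMR Calling, Remethylation Metrics and Co-Purification Proteomics for
    Methyltransferase-Deficient Hematopoiesis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis toolkit for whole-genome bisulfite comparisons of
    DNA-methyltransferase-deficient bone marrow: differentially methylated
    region (DMR) calling by recursive binary segmentation with
    Mann-Whitney testing and Benjamini-Hochberg control, passive DMR
    methylation matrices, unified DMR sets, aggregate canyon profiles,
    annotation-class summaries, floxing-efficiency estimation from
    coverage dropout, quantification of remethylation after
    methyltransferase addback, splice-junction isoform-usage testing, and
    a PSM-level proteomics ratio-normalization pipeline (recursive Dixon
    outlier removal, median roll-ups, Gaussian-mixture mode alignment,
    trimmed-SD scaling, intensity calibration, and co-purification
    stoichiometry). Includes a seeded synthetic-data generator emulating
    the statistical structure of the real data so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors,
    SummarizedExperiment,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
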