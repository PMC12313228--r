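Package: spoiq
Title: Quantifying Tumor Invasion Pattern and Partial-EMT State in 3D Organ Cultures
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying head and neck squamous cell carcinoma
    (HNSCC) invasion in organotypic 3D cultures from immunofluorescence
    images, and for scoring the partial epithelial-mesenchymal transition
    (p-EMT) state of keratinocyte populations from qPCR data. Implements
    segmentation of the epithelial sheet and detached tumor islands,
    per-island nuclei counting, the invasion index, worst pattern of
    invasion (WPOI) grading, the single pattern of invasion (SPOI)
    statistic, a nine-gene delta-Ct p-EMT score, and the association
    analyses (correlation with regression, paired t-tests, iterative
    Grubbs outlier flagging, TGF-beta responder classification, and a
    transcription-factor invasion screen) that connect invasion phenotype
    to p-EMT state. A synthetic-data module generates all input kinds
    with exact ground truth so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    readr,
    generics,
    jsonlite,
    yaml,
    withr,
    tiff,
    png,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
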