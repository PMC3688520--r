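Package: polystate
Title: Differential Protein Occupancy and Cohesin-Polycomb Chromatin States
    from Tiling-Array ChIP
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantitative comparison of protein occupancy on
    tiling-array ChIP enrichment tracks between RNAi-depleted and control
    conditions in Drosophila cells. Calls bound intervals by run-length
    thresholding of probe scores, calls signed differential-occupancy
    intervals against a genome-wide delta null distribution, computes
    RNA polymerase II pause indices and Ser2P/Rpb3 elongation ratios,
    classifies genes into cohesin-Polycomb chromatin states, and
    normalizes chromosome conformation capture (3C) qPCR interactions
    against a randomly religated BAC control. Includes a seeded synthetic
    tiling-array generator that provides ground truth for every stage.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
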