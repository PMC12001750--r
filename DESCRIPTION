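Package: adenoscreen
Title: Blood-Based Detection of Advanced Colorectal Adenomas from cfDNA and Plasma Proteins
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for blood-based detection of advanced colorectal adenomas
    from plasma assays. Implements a cfDNA fragmentation classifier built on
    per-arm non-negative matrix factorization of amplicon read counts
    ("signatures of fragment length"), a chromosome-arm aneuploidy score
    trained with in-silico aneuploid samples, a 17-analyte plasma protein
    score, and a partitioned multi-well mutation-detection statistic with an
    empirical background-noise model and Monte-Carlo p-values. An evaluation
    layer calibrates positivity thresholds at a target specificity, combines
    assays under an any-positive rule, and reports sensitivity and
    specificity with Wilson score intervals. Synthetic-data generators
    emulate amplicon count matrices with batch effects, fragmentation tilt
    and arm-level aneuploidy, plasma protein panels, and multi-well mutation
    read tables, so every stage can be trained and tested without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    pracma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
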