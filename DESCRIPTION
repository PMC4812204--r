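Package: sigreverse
Title: Transcriptomic Signature Reversal Screening Against Drug
    Perturbation Rank Databases
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Builds disease gene-expression signatures from log2
    expression matrices (moderated-t differential expression with
    Benjamini-Hochberg control, fold-change filtering, largest-changing
    probe queries) and screens them against a Connectivity-Map-style
    database of rank-transformed drug perturbation profiles using two
    complementary scores: the Kolmogorov-Smirnov tag-enrichment
    connectivity score and a set-overlap reversing score on
    median-condensed gene ranks.  Candidate reversers are clustered by
    the genes they reverse, reversed gene sets are tested for gene-set
    over-representation with Fisher's exact test, and a synthetic-data
    module generates expression matrices and rank databases with planted
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    limma,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
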