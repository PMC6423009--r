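Package: clonarch
Title: Clonal Architecture Analysis of Tumor Cohorts from Cancer Cell Fractions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Reconstructs the clonal architecture of tumor cohorts from somatic
    mutation calls and copy-number segments. Estimates cancer cell fractions
    (CCFs) for single-nucleotide variants and arm-level somatic copy-number
    alterations with a binomial grid posterior, classifies events as clonal or
    subclonal, extracts trinucleotide mutational signatures by alternating
    least-squares non-negative matrix factorization with bootstrap rank
    selection, tests clonal/subclonal enrichment by permutation, orders driver
    acquisitions in time from within-patient clonal-subclonal co-occurrence,
    subtypes patients by consensus NMF of event CCFs with cophenetic rank
    selection, and relates subtypes to survival and immune infiltration
    (Kaplan-Meier curves, Cox regression, single-sample gene-set enrichment).
    Includes a synthetic-cohort generator with planted ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    survival,
    pracma,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    Biostrings,
    fgsea,
    yaml,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
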