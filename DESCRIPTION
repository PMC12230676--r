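Package: bgcscout
Title: Rule-Based Detection and Annotation of Biosynthetic Gene Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects biosynthetic gene cluster (BGC) regions in annotated
    microbial genomes from profile hidden Markov model (pHMM) hit tables
    using a declarative rule language, with first-class support for
    circular replicons and origin-spanning clusters. Detected regions are
    annotated further: nonribosomal peptide synthetase (NRPS) and
    polyketide synthase (PKS) domains are assembled into biosynthetic
    modules with catalytic-residue checks for condensation and
    epimerization domains; terpene synthases are classified to product
    class, chain length and, where known, product name; tailoring enzymes
    are grouped by Enzyme Commission category with identity-thresholded
    cross-links to a reaction reference set; and regions are compared to
    known reference clusters with three-tier confidence binning. Ships a
    deterministic synthetic fixture generator so the whole pipeline is
    testable without external databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
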