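Package: infosig
Title: Informative Mutational Signatures from Explainable Cancer-Type
    Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds explainable cancer-type classifiers from somatic
    single-nucleotide variant catalogs. Extracts trinucleotide-context
    mutation features (96 + 48 + 6 classes under pyrimidine collapsing),
    megabase-bin mutation densities and per-gene mutation counts; trains a
    class-weighted feed-forward neural network under stratified
    cross-validation; explains predictions with layer-wise relevance
    propagation (epsilon rule); and combines per-class mutation frequency
    profiles with positive median feature relevance into informative
    mutational signatures, including relevance-weighted signature distances
    and reference-catalog combination fitting. A synthetic-cohort simulator
    with known ground-truth signature mixtures makes the whole pipeline
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    IRanges,
    purrr,
    readr,
    rlang,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    vcfR,
    withr
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
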