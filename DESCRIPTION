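Package: rnctools
Title: Mapping Cotranslational Chaperone Specificity from
    Ribosome-Nascent-Chain Immunopurification Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: An analysis pipeline for ribosome-nascent-chain (RNC)
    immunopurification experiments that profile which mRNAs are engaged by
    cotranslationally acting factors (ribosomal proteins, the signal
    recognition particle SRP, the nascent-chain-associated complex NAC, and
    membrane fractions). Provides spot-quality and missing-value filtering of
    replicated log2(IP/reference) ratio tables, a one-class SAM permutation
    test with q-value false discovery rates, target-set calling, target-set
    algebra (SRP/membrane quadrants, NAC-dependence classes, NAC dimer
    substrate assignment), Kyte-Doolittle hydropathy profiling with
    hydrophobic-stretch detection, hypergeometric annotation-term enrichment,
    descriptive summaries (Pearson correlation, hierarchical clustering,
    cumulative fractions, box-plot statistics), and a synthetic-study
    generator with planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
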