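Package: syncordance
Title: Multi-Omics Fold-Change Concordance for Synaptosomal Proteomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Links a synaptosomal proteome change to whole-tissue, synaptosome
    input and synaptic polysome transcriptome layers via balanced ranked-subset
    correlation sweeps and a directional (up/down) decomposition, plus
    gene-list overlap statistics against a scaffold interactome. Includes a
    negative-binomial synthetic-data generator that emulates a
    scaffold-driven local-translation causal structure so every stage of the
    pipeline can be validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
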