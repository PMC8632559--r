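Package: commdelta
Title: Multi-Condition Cell-Cell Communication Comparison and Multiscale
    Signaling Network Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compares ligand-receptor mediated cell-cell communication
    networks inferred from single-cell expression data across any number of
    conditions (interaction counts, in/out interaction strength, pathway
    information flow, Jaccard functional similarity with joint embedding and
    clustering), and links intercellular signaling to intracellular response
    by inferring a transcription-factor to target-gene regulatory network
    with a prior-network-regularized sparse regression solved by the
    alternating direction method of multipliers (ADMM). The regression
    estimate is ensembled with a proportionality-based association measure
    and assembled, together with a receptor-TF prior, into a layered
    ligand-receptor-TF-target multiscale signaling graph restricted to cell
    type enriched regulators. A synthetic-data generator with planted ground
    truth makes the whole pipeline testable without external datasets.
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
    Matrix,
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
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
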