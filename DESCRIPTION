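Package: ccinet
Title: Ecological Network Analysis of Multilayer Chaperone-Client Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing chaperone-client interaction (CCI) networks as
    multilayer bipartite ecological networks, where each layer is one cellular
    environment (for example, one cancer type). Builds binary interaction layers
    from gene-expression matrices by Spearman coexpression with Bonferroni
    correction and sample-size-matched bootstrap consensus; computes ecological
    niche statistics (specialization, realized niche, partner fidelity, niche
    overlap); measures weighted nestedness as the spectral radius of the
    realized-niche matrix with significance against curveball fixed-margin null
    ensembles; fits a multilayer mixed-membership stochastic block model by
    expectation-maximization with BIC model selection; predicts held-out links
    within and across layers (AUC); and simulates co-extinction robustness of
    clients under targeted and random chaperone removal. Includes a synthetic
    data generator with planted block structure so the whole pipeline is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
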