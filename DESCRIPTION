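Package: symbioweb
Title: Endosymbiont Effects on Aphid-Parasitoid-Hyperparasitoid Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for individual-level field surveys of cereal
    aphids screened for facultative bacterial endosymbionts (Hamiltonella
    defensa, Regiella insecticola, PAXS), primary parasitoids and
    hyperparasitoids. Provides sample classification and community-table
    construction with occurrence filters, a hierarchical synthetic-data
    generator emulating a multi-field plot design with endosymbiont-mediated
    parasitoid mortality, the H2' network specialization index family with an
    exact enumeration oracle, a resampled bipartite food-web procedure with
    covariate propagation and AIC-based linear modelling, Bray-Curtis SIMPER
    decomposition and partial distance-based redundancy analysis with
    permutation tests, and hierarchical bootstrap rate estimation with
    FDR-corrected contrasts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    vegan,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
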