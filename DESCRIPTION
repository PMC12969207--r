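Package: sfcnet
Title: Multiscale Structure-Function Coupling Analysis of Brain Connectomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Computes regional, network-level and whole-brain
    structure-function coupling (SFC) from paired functional and structural
    connectomes, performs covariate-adjusted two-group inference with
    Bonferroni correction, validates findings with graph-theoretic network
    topology (small-worldness, efficiency, nodal metrics over a sparsity
    sweep), relates the regional group t-map to regional gene expression via
    first-component partial least squares with permutation and bootstrap
    inference, and tests spatial Spearman correlations with
    receptor/transporter density maps by region permutation with FDR
    control. Ships a synthetic-cohort generator with planted coupling
    deficits, map-coupled genes and receptor maps, so every stage has a
    recovery test without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    mixOmics,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
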