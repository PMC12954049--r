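Package: oubranch
Title: Hybrid Ornstein-Uhlenbeck and Branching Models for Replicate
    Phenotype Trajectories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Exact-transition Ornstein-Uhlenbeck (OU) likelihood inference
    for replicate-grouped phenotype time series such as log10 mutation
    frequencies from evolution experiments, with multi-restart maximum
    likelihood, replicate bootstrap, profile-likelihood surfaces, and
    shared-versus-lineage-specific model comparison (LRT, AIC).
    Gaussian-predictive trajectory-separation metrics (mean separation,
    2-Wasserstein distance, dominance probability) with bootstrap
    propagation. Forward simulators coupling the OU trait to birth-death
    demography: constant-rate Gillespie birth-death, phenotype-coupled
    lineage networks with GraphML export, phase-plane dynamics, and
    cyclic-therapy ensembles with cure-probability maps.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    igraph,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
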