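Package: fibrotwin
Title: Atrial Digital-Twin Pipeline for Fibrosis Synthesis, AF Simulation
    and Ablation-Outcome Prediction
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Desk-scale in-silico pipeline for atrial fibrillation (AF)
    research on 2D universal-atrial-coordinate fibrosis maps. Generates
    synthetic late-gadolinium-enhancement-like fibrosis distributions with a
    from-scratch denoising diffusion probabilistic model, quality-filters
    them with spatial statistics (normalized Shannon entropy, Moran's I),
    translates image-intensity-ratio maps into remodeled tissue (conductivity
    bins, ionic conductance scalings, ablation masks), simulates AF episodes
    with a monodomain solver coupled to a modified Courtemanche atrial
    myocyte model, extracts dominant-frequency and phase-singularity-density
    feature maps, and trains a Siamese two-head classifier with
    outer-arithmetic fusion (MOAB/FOAA) to predict termination after four
    ablation strategies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    jsonlite,
    yaml,
    ggplot2,
    generics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    deSolve,
    pROC,
    ape,
    pracma,
    tidyr
Config/testthat/edition: 3
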