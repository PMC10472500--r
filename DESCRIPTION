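Package: engramfield
Title: Ephaptic Coupling Analysis for Neural Ensemble Recordings
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for detecting ephaptic coupling (the feedback of emergent
    extracellular electric fields onto neural activity) in multi-electrode
    ensemble recordings. Provides a deep neural field simulator of
    cue-conditioned delay-period activity on a one-dimensional cortical patch,
    a bidomain forward model of the extracellular potential and electric
    field, restricted maximum-likelihood fitting of the field model's Gaussian
    linear reformulation with Free-Energy based Bayesian model comparison of
    ephaptic versus non-ephaptic generative models, snapshot-based ("spatial")
    Granger causality between field and activity profiles and between areas,
    representational similarity analysis of memory representations across
    areas, Fourier-mode slaving diagnostics with a two-area linear stability
    analysis, and an end-to-end pipeline that exercises all stages on
    synthetic data.
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
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
VignetteBuilder: knitr
Config/testthat/edition: 3
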