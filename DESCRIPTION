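Package: subunitscope
Title: Inference of Localized Subunit Filters in Visual Cortical Neurons
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and system-identification toolkit for studying how
    direction selectivity is constructed in primary visual cortex. Provides
    generators for the classical stimulus ensembles (binary m-sequence bar
    movies, drifting sinusoidal gratings, 1/f pink-noise movies) and for
    model neurons ranging from linear-nonlinear simple cells to
    energy-model and pooled-subunit complex cells with Poisson spiking.
    The estimation side implements spike-triggered average and covariance
    analysis with shuffle-based significance testing, PCA whitening for
    correlated stimuli, a spatial-localization search that rotates the
    spike-triggered covariance subspace into spatially compact subunit
    filters, sparse (L1-logistic) selection of relevant filters, a
    generalized nonlinear cascade model fit by penalized Poisson maximum
    likelihood, and prediction of direction-selectivity and modulation
    indices from fitted models and filter spectra.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite,
    yaml,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
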