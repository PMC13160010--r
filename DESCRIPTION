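Package: bcidamp
Title: Closed-Loop Error Damping for Intracortical BCI Cursor Control
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis toolkit for closed-loop error damping in
    intracortical brain-computer interface (BCI) cursor control. Generates
    synthetic center-out BCI sessions with Poisson-spiking motor-cortex
    channels, a pre-leading error-related neural latent and session-specific
    directional control biases; calibrates a factor-analysis plus
    Kalman-filter velocity decoder in two steps; labels correct, pre-error and
    erroneous control from cursor-to-target kinematics; trains a
    pooled-variance naive Bayes error classifier evaluated by cross-validation
    across time and across targets; applies real-time velocity damping when
    the error probability crosses a threshold; and reproduces the offline
    population analyses (subspace alignment index with chance level, PCA
    dimensionality, participation ratio, Gaussian mutual information, linear
    motor-intent reconstruction, LDA projection) together with the standard
    closed-loop performance metrics.
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
    graphics,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    e1071,
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
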