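Package: band
Title: Behavior-Aligned Neural Dynamics for Spiking Populations
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Semi-supervised latent dynamics modelling of trial-aligned
    spiking neural population recordings. Implements a sequential
    variational autoencoder with a Poisson observation model, an initial-
    condition encoder restricted to the preparatory window, a causal
    controller inferring per-bin control inputs during movement, and a
    jointly trained sequence-to-sequence linear behavior decoder
    (behavior-aligned neural dynamics, BAND), together with its
    unsupervised and controller-ablated variants. Includes a center-out
    reach simulator with oscillatory motor corrections and lagged
    sensory feedback, evaluation metrics (Poisson likelihood, bits per
    spike/second, isotropic R-squared, explained behavior variance),
    cross-validation, a desk-scale population-based training loop, and
    analyses of oscillations, decoder-weight lag structure, and
    controller contributions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
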