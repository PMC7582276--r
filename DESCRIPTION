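Package: tmagrl
Title: Self-Recalibrating Neural Decoding with Attention-Gated Reinforcement Learning
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building and evaluating self-recalibrating classifiers
    for intracortical brain-machine interfaces. Implements the attention-gated
    reinforcement-learning (AGREL) network with reward-modulated Hebbian
    plasticity, PCA-based unsupervised domain adaptation for session-to-session
    transfer, confidence-gated initial training, and mini-batch online weight
    updating from a FIFO buffer of recently tested trials (the TMAGRL scheme).
    Includes a nonstationary Poisson spike-count session simulator with
    day-to-day tuning drift, static and retrained kernel-classifier baselines,
    bootstrap-based evaluation protocols, and a command-line interface for
    reproducible benchmark runs.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
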