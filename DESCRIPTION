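Package: mapca
Title: Multi-Source Model Adaptation with Possibilistic Clustering for
    Semi-Supervised Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Graph- and kernel-based semi-supervised classification with
    possibilistic (fuzzy-entropy regularized) cluster memberships and
    divergence-constrained multi-source model adaptation (MA-PCA). Builds
    k-nearest-neighbour graphs with Gaussian edge weights and local weighted
    means, fits a kernel ridge decision model by alternating closed-form
    updates of dual coefficients, per-class possibilistic memberships, and
    simplex-constrained source weights, and ships a synthetic multi-domain
    generator, ablation weighting schemes, a leave-one-domain-out evaluation
    harness, and a command-line interface. Designed for EEG-style real-valued
    feature vectors (e.g. differential-entropy features) where labelled data
    are scarce and training/test distributions differ across subjects or
    recording sessions.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    data.table,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
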