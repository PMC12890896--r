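Package: clforget
Title: Order Parameters and Phase Transitions of Continual Learning in Wide Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analytically grounded simulators and diagnostics for catastrophic
    forgetting in deep, wide neural networks. Provides task-relation order
    parameters (feature overlap, relevant-feature similarity, rule similarity,
    and the multihead similarity score) computed from explicit random ReLU
    features or from their exact infinite-width arc-cosine (NNGP) kernel
    limit; parametric task-sequence generators (target-distractor,
    permutation, split protocols); single-head sequential minimum-change
    interpolation with forgetting curves and exponential-relaxation fits; a
    multihead two-task trainer with a weight-perturbation penalty, phase
    classification into fixed-representation, overfitting, and generalization
    regimes, and the critical-load prediction from the similarity score.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    yaml,
    optparse,
    ggplot2
Config/testthat/edition: 3
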