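Package: eghr
Title: Error-Gated Hebbian Rule for Multi-Context Blind Source Separation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulators, trainer, metrics and theory for blind source
    separation (BSS) with the error-gated Hebbian rule (EGHR), a biologically
    plausible three-factor plasticity rule that solves independent component
    analysis with redundant (undercomplete) sensory inputs. Generates
    unit-variance Laplace source trains and every mixing-matrix regime of the
    multi-context BSS task (static per-context matrices, rotating and
    Ornstein-Uhlenbeck-driven time-varying mixtures, Markov-switching
    dynamics, and context-vector mixing), trains a linear network with the
    EGHR, evaluates recovery with the source-to-output transform matrix and
    its BSS error, constructs reference solutions and linear-stability
    coefficients from the underlying theory, and contrasts against
    conventional ICA baselines (natural gradient, non-holonomic, ICA mixture)
    that cannot reduce dimensionality.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    ggplot2,
    generics,
    rlang,
    stats,
    utils,
    yaml,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
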