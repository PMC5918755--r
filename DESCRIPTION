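Package: stigmasim
Title: Agent-Based Simulation of Intergroup Trust, Prejudice and Conformity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates the dynamics of trust between a dominant and a
    subordinate group in an artificial society. Agents repeatedly play a
    two-strategy coordination game in randomly sampled dyads, act on their
    beliefs about the partner's group, and update those beliefs by
    exponential smoothing. Learning rates are either constant or modulated
    by social conformity, where an agent's learning speed equals the
    distance of its belief from a distance-weighted group norm. The package
    provides scenario presets, enlightenment interventions (instantaneous
    and gradual generational replacement), log-spaced trajectory recording,
    summary statistics (convergence time, unrecovered trust,
    decline/recovery ratio), tidy accessors and ggplot2 visualisations, and
    a command-line interface for batch runs.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
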