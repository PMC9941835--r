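Package: cavclamp
Title: Whole-Cell Voltage-Clamp Analysis and Simulation of Cav1.3 Channel Gating
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for whole-cell patch-clamp recordings of
    voltage-gated L-type calcium (Cav1.3) channels, paired with a
    Hodgkin-Huxley-style synthetic current generator. Builds the standard
    voltage-command protocol families (current-voltage, steady-state
    inactivation, 5-s inactivation, two-pulse recovery, tail-current and
    pharmacology trains), simulates whole-cell currents with leak, run-down
    and Hill-type drug block, performs P/4 and offline linear leak
    subtraction, and fits the field's canonical descriptions: Boltzmann
    activation and modified-Boltzmann inactivation curves, window current,
    mono/bi-exponential decay with extra sum-of-squares model selection,
    double-exponential recovery from inactivation, tail-current deactivation
    and run-down-corrected concentration-inhibition (IC50) curves. Results
    are tibbles and broom-style tidied fit objects with ggplot2 autoplot
    methods.
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
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
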