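Package: udsvr
Title: Uniform-Design Plus Support-Vector-Regression Optimization of
    Multi-Factor Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Sequential optimization of multi-factor, multi-level
    experiments (fermentation media and process parameters in
    particular) by coupling mixed-level uniform experimental designs
    with an epsilon support-vector-regression surrogate. Provides
    good-lattice-point construction of U-type designs scored by the
    centered L2-discrepancy, cross-validated kernel/C/gamma grid
    search, backward nonlinear feature screening on cross-validated
    mean squared error, exhaustive prediction over all level
    combinations of the retained factors, frequency-based selection of
    promising levels with boundary-extrapolation rules, and planning of
    the next experimental round. A synthetic response-landscape
    generator makes every stage testable in silico.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    e1071,
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
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
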