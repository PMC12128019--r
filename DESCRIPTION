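Package: spinfep
Title: Alchemical Free Energy Perturbation for Singlet-Triplet Spin Conversions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes singlet-to-triplet free-energy differences by alchemical
    free energy perturbation over lambda-mixed two-state Hamiltonians. Provides
    Langevin (BAOAB) and exact canonical sampling of mixed states, the Zwanzig
    exponential-averaging estimator with first-order (Chipot) error bars
    corrected for serial correlation via the lag-1 autocorrelation sampling
    ratio, the endpoint internal-energy (Delta-U) baseline it is designed to
    outperform, Mulliken spin-population localization analysis, and synthetic
    two-state systems with analytic and quadrature free-energy oracles for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
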