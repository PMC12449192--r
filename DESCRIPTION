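Package: xanthoq
Title: Xanthophyll-Cycle Kinetics and Non-Photochemical Quenching Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of xanthophyll-cycle-driven non-photochemical
    quenching (NPQ) in diatoms. Provides pigment-pool metrics and de-epoxidation
    states for the diadinoxanthin and violaxanthin cycles, NPQ/qE computation from
    pulse-amplitude-modulated fluorescence under the low-light reference convention,
    first-order and consecutive (Bateman) re-epoxidation kinetics fitting,
    candidate de-epoxidized-pool regression against qE, per-time-point Welch tests
    with Holm correction, and a genotype-aware mechanistic simulator of both
    xanthophyll cycles under high-light/low-light regimes that generates
    replicate-level synthetic datasets for every analysis stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
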