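Package: doublepass
Title: Double-Pass Decomposition of Stochastic and Deterministic Errors in
    Visual Search
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the double-pass analysis of miss errors in visual
    search. Generates T-among-L search designs (uniform or 1/f^1.3 noise
    backgrounds, controlled target-background contrast), simulates trial-level
    behavior under a four-state latent model with known deterministic and
    stochastic error rates, applies reaction-time and d-prime exclusion rules,
    and estimates the proportion of deterministic errors (d) and per-round
    stochastic miss rates (s1, s2) from the observed repeat-miss rates
    (P1, P2, P12) via closed-form solvers, including the cued-second-pass
    variant. Cohort-level t-tests, contrast-binned hit rates and
    observed-versus-predicted tables mirror the standard reporting of the
    paradigm.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    png,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    withr
Suggests:
    knitr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
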