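Package: promleak
Title: Stochastic Gene Expression with Promoter Leakage and Auto-Regulation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the two-state (telegraph) gene auto-regulatory model in
    which the inactive promoter state retains a low residual synthesis rate
    (promoter leakage). Provides the closed-form stationary copy-number
    distribution expressed in confluent hypergeometric functions together with
    generating-function moments and noise intensity, an independent
    steady-state solver for the truncated chemical master equation, an exact
    Gillespie simulator of the reaction network (with slow transcription-factor
    binding and two-stage transcription/translation variants), burst-kinetics
    summaries (burst size, burst frequency, promoter dwell times), and scan
    drivers for studying how leakage shapes expression noise, distribution
    modality and bursting.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
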