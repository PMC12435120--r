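Package: adaptscreen
Title: Analytic Bounds for Adaptive AI-Triaged Breast MRI Screening Protocols
Version: 1.0.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Analytic model of an adaptive breast MRI screening policy in
    which an AI reader decides, immediately after an abbreviated protocol,
    whether to continue with the full protocol. Computes recall-rate and
    expected-protocol-duration values for abbreviated-only and full-only
    strategies, and sharp best-/worst-case limits for the adaptive strategy
    from stratified Frechet-Hoeffding bounds on radiologist/AI agreement.
    Includes one-at-a-time parameter sweeps with breakpoint detection, a
    "most likely" performance band driven by a literature agreement-accuracy
    interval, a seeded Monte-Carlo / expected-count cohort simulator that
    validates the analytic bounds, and a command-line interface with CSV,
    JSON and figure output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
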