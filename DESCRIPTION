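Package: m4rhfunnel
Title: Conversion-Funnel and Engagement Analytics for On-Demand SMS Health Services
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for process evaluation of on-demand ("pull") SMS health
    information services from their raw query logs, developed around the m4RH
    (Mobile for Reproductive Health) deployment in Tanzania. Parses and cleans
    inbound-message logs (invalid queries, successive duplicate menu selections,
    misspelled service keywords), reconstructs per-user journeys through a
    hierarchical menu catalog, and computes conversion-funnel indicators
    (activation, active use, conversion, churn) together with loyalty and
    interaction metrics (new/return/repeat users, acquisition, time-of-day
    profiles, inter-query durations, content depth shares, ward-level clinic
    lookups, promotion association). A generative simulator of m4RH-like logs
    with known ground truth supports end-to-end validation and parameter
    recovery without access to any real subscriber data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    lubridate,
    readr,
    stringr,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
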