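Package: cataractsim
Title: Discrete Event Simulation of Hospital Cataract Surgery Services
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A process-oriented discrete event simulation of an NHS hospital
    cataract service, from optometrist referral through eye examination,
    pre-operative assessment, theatre-list scheduling, surgery and recovery to
    day-case discharge. Models half-day theatre sessions with a fixed number of
    patients per list, same-day cancellation and no-show dynamics with the
    lost-slot rule for elective surgery, and resource pools (doctors, nurses,
    consultation and pre-surgery rooms, recovery chairs and beds). Computes
    monthly and annual key performance indicators (surgeries, staff hours,
    resource utilisation) and tariff-based finance (revenue, cost, surplus),
    and evaluates what-if scenarios that increase the number of surgeries per
    theatre list. Ships a synthetic parameter set and calibration utilities so
    the whole pipeline runs without access to confidential hospital data.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    knitr,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
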