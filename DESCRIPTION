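Package: rxwindows
Title: Climatology of Prescribed-Fire Burn Windows from Gridded Daily Weather
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies "burn windows" -- days on which surface weather and
    dead fuel moisture fall inside the envelope of operational burn
    prescriptions -- from daily gridded meteorology. Implements NFDRS-style
    equilibrium moisture content, 1/10/100/1000-hour dead fuel moisture and
    ignition component; median prescription envelopes built from forest and
    non-forest burn-plan sets with binary in-prescription (RxDay)
    classification per grid-day; empirical quantile-mapping bias correction
    of model-derived fire-danger metrics; low-level air-stagnation day
    counts; and seasonal, annual and regional count climatologies with
    linear trends, epoch differences and ensemble agreement. A stochastic
    weather generator (seasonal cycles, AR(1) anomalies, secular trends,
    Bernoulli-gamma precipitation, pseudo-model ensembles) makes the whole
    chain testable without external archives.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    ncdf4,
    stats,
    utils,
    yaml
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
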