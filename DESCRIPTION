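Package: pvkit
Title: Pharmacovigilance Signal Detection and Time-to-Onset Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for mining spontaneous adverse-event reporting system
    data. Reads FAERS-style quarterly ASCII extracts and generic CSV
    dialects, applies case-level deduplication and primary-suspect
    filtering, builds drug-event contingency tables at the MedDRA
    preferred-term or system-organ-class level, and screens signals with
    four disproportionality algorithms: the reporting odds ratio, the
    proportional reporting ratio with chi-squared test, the BCPNN
    information component, and the DuMouchel multi-item gamma-Poisson
    shrinker (EBGM). Includes Weibull time-to-onset modelling with
    hazard-pattern classification, Kaplan-Meier cumulative incidence,
    cross-database signal overlap, network-pharmacology set and graph
    statistics (betweenness hubs, hypergeometric over-representation),
    and a synthetic reporting-system generator with planted signals for
    end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    withr,
    survival,
    igraph
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    jsonlite
Config/testthat/edition: 3
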