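Package: faerspv
Title: Disproportionality Signal Detection for FAERS Spontaneous Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for pharmacovigilance signal detection on FDA Adverse
    Event Reporting System (FAERS) quarterly ASCII data: ingestion of the
    "$"-delimited DEMO/DRUG/REAC/THER tables, case deduplication by the
    FDA-recommended rule, primary-suspect filtering, construction of
    two-by-two contingency tables at the MedDRA preferred-term and
    system-organ-class levels, four disproportionality statistics (reporting
    odds ratio, proportional reporting ratio, information component, and
    relative reporting ratio with lognormal limits) with positivity
    thresholds, demographic descriptives, multi-drug comparison, Weibull
    time-to-onset modelling, and a seeded synthetic-report generator with a
    closed-form expected-count oracle for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table,
    jsonlite,
    stats,
    utils
Suggests:
    fitdistrplus,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
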