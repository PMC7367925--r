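Package: navitro
Title: Cross-Laboratory In Vitro Toxicology Data Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Toolkit for running a new-approach-method (NAM) in vitro test
    battery across laboratories: a validated plain-text plate-data format with
    full metadata, solvent-control normalization and baseline-variance quality
    control (relative standard deviation of technical replicates,
    negative-control spread), four-parameter log-logistic concentration-response
    fitting with benchmark-concentration (BMC) and point-of-departure (PoD)
    derivation in a unified -log10(M) convention, cytotoxicity anchoring of
    functional hits, mass-balance prediction of the free (unbound) compound
    concentration in arbitrary culture media from albumin and lipid content,
    fit-for-purpose test-method readiness scoring, and a deterministic
    synthetic-plate generator with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
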