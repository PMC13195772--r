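Package: aafmort
Title: Alcohol-Attributable Mortality Estimation from Survey and Registry Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Estimates alcohol-attributable mortality from survey-based
    exposure data and cause-of-death registries. Converts AUDIT-C style
    survey items into per-stratum exposure distributions (drinker-status
    prevalences and a gamma consumption model calibrated to per-capita
    benchmarks), evaluates parametric relative-risk curves, computes
    alcohol-attributable fractions by continuous-risk integration with
    heavy-episodic-drinking stratification, attributes ICD-10 coded deaths,
    produces crude and age-standardized rates, and propagates sampling and
    coefficient uncertainty through the pipeline by Monte Carlo simulation.
    Includes a synthetic-data generator with exportable ground truth so the
    full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    fitdistrplus,
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
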