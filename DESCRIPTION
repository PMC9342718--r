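Package: livesaved
Title: Deterministic Lives-Saved and Missed-Opportunity Modelling of
    Under-Five Mortality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A deterministic, multi-cause model of under-five mortality for
    evaluating child-health intervention portfolios. Converts live births and
    baseline neonatal/under-five mortality rates into expected cause-specific
    deaths in two age bands, applies intervention coverage through the
    standard impact formula (coverage change x effectiveness x affected
    fraction) with multiplicative combination within a cause, scales
    infectious-cause mortality by stunting and wasting prevalence via mean
    relative risks, and attributes deaths averted to individual interventions
    by exact-summing signed log-residual shares. Ships three scenario
    runners (baseline-to-endline evaluation, one-at-a-time missed-opportunity
    ranking at a coverage threshold, and universal scale-up with
    counterfactual mortality rates), a seeded synthetic country-profile
    generator with closed-form ground truth, reproducible table renderers,
    and a published Ghana 2008-2014 evaluation's printed tables as
    plain-text fixtures.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
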