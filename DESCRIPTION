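Package: acescreen
Title: Cost-Utility Analysis of Laboratory Screening in Acquired Comitant Esotropia
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic cost-utility model comparing universal, targeted,
    and no routine laboratory screening (acetylcholine receptor antibody and
    thyroid function tests) in acquired comitant esotropia. Couples a
    diagnostic-outcome decision tree (prevalence x sensitivity/specificity)
    to an annual-cycle Markov cohort model with half-cycle correction and
    discounting, and reports incremental cost-effectiveness ratios and net
    monetary benefit against willingness-to-pay thresholds. Includes one-way
    deterministic sensitivity analysis with tornado ordering, probabilistic
    sensitivity analysis with beta/gamma parameter distributions,
    cost-effectiveness acceptability curves, a two-way price-prevalence
    threshold analysis, and a synthetic patient-cohort generator for
    end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
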