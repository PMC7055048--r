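Package: eurofitce
Title: Markov Cohort Cost-Effectiveness Model of the EuroFIT Physical
    Activity Programme
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decision-analytic cost-effectiveness model comparing the EuroFIT
    physical-activity programme for male football fans with no intervention.
    Implements a nine-state Markov cohort model (three physical-activity
    levels, five chronic conditions, death) with annual cycles, computes
    discounted costs and quality-adjusted life years over a five- or ten-year
    horizon, and propagates parameter uncertainty by probabilistic sensitivity
    analysis with cost-effectiveness acceptability curves. Ships the full
    published parameter set as a structured configuration file, deterministic
    and probabilistic scenario analyses (time horizon, costing perspective,
    utility source, duration of the intervention effect, discount rates), and
    a synthetic-trial generator that emulates the randomised-trial data from
    which the activity-transition probabilities are estimated.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tools,
    utils,
    yaml
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
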