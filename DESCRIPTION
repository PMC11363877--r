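Package: netscaleup
Title: Network Scale-Up Estimation of Hidden Population Sizes
Version: 0.1.0
Authors@R: person("Netscaleup", "Maintainers", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for estimating the size of hidden or hard-to-reach
    populations with the network scale-up method (NSUM). Implements
    known-population estimation of personal network size, unmasking of
    sensitive alter counts collected with the unrelated-question
    quantitative randomized response technique, the basic scale-up
    estimator, adjustment for barrier effects and transmission error via
    the popularity ratio and information transmission rate measured in a
    respondent-driven sampling (RDS) survey of the hidden population,
    percentile bootstrap confidence intervals (respondent, cluster and
    recruitment-chain flavors), and a fully parameterized synthetic survey
    generator so the whole pipeline can be validated by simulation.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
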