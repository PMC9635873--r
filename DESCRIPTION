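Package: adaptcond
Title: Associative-Learning Analysis of Sensorimotor Adaptation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulation and analysis tools for studying sensorimotor adaptation
    through the lens of classical conditioning. Implements Rescorla-Wagner and
    state-space simulators of clamped-feedback reaching experiments (differential
    and compound conditioning designs), a synthetic-participant generator,
    trial-by-trial heading-angle preprocessing and effects analyses (Pavlovian
    and adaptation contrasts, repeated-measures ANOVA, binned dynamics
    regression, Friedman/overshadowing analyses), and multi-start bounded
    least-squares model fitting with AIC comparison.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    tibble,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
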