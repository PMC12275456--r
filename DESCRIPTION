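Package: sfepower
Title: Simulation-Based Power Analysis for Semi-Field Vector Control Experiments
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for designing semi-field experiments (SFEs) that evaluate
    malaria vector control interventions such as insecticide-treated nets and
    pyriproxyfen autodissemination. Mosquito-count data are simulated from
    Poisson generalized linear mixed models with a chamber random intercept
    (short-term experiments) or negative-binomial models with crossed chamber
    and time random intercepts (long-term experiments); the models are refitted
    by maximum likelihood (adaptive Gauss-Hermite quadrature, Laplace
    approximation) and statistical power and type-I error are estimated by
    Monte Carlo simulation across grids of design choices: chambers per
    treatment, expected mosquitoes recaptured, sampling frequency,
    inter-chamber variance and target effect size.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    lme4,
    glmmTMB,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
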