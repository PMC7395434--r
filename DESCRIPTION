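Package: crdgame
Title: Simulation and Analysis of Collective-Risk Social Dilemma Experiments
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Tools for simulating and analysing threshold public-goods games
    under collective risk, of the kind used in experimental studies of climate
    change mitigation. Provides the exact game mechanics (fixed endowment,
    discrete contribution menu, group target, probabilistic loss on failure),
    a staged yes/no communication protocol with majority-only display,
    generative behavioural-type agents (cooperators, free riders, altruists)
    calibrated to published population means and round trends, a synthetic
    experiment generator matching the published study design, exact and
    Monte-Carlo characterisations of the random-play null model with
    significance envelopes for failing groups, and the standard analysis
    pipeline: three-way contingency tables with the nine hierarchical
    log-linear models, two-way ANOVA of per-capita investment, hierarchical
    clustering into behavioural types, per-type trend regression and ANCOVA,
    multinomial investment-choice models, exact binomial tests, and multiple
    correspondence analysis of the questionnaire.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    tibble,
    purrr,
    rlang,
    ggplot2,
    readr,
    jsonlite,
    stats,
    utils,
    nnet,
    car,
    generics,
    withr
Suggests:
    testthat (>= 3.0.0),
    MASS
Config/testthat/edition: 3
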