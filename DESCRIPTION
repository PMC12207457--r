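Package: crdelegate
Title: Simulation and Analysis of Delegated Collective-Risk Dilemmas
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for threshold public-goods experiments in which
    participants either play a collective-risk dilemma themselves or program
    an artificial delegate (a starting action, two conditional reaction tables
    and a public-account switch) to play on their behalf. Provides a
    deterministic game engine with stochastic risk resolution, a synthetic
    population generator emulating observed behavioral profiles and
    between-game revision, group and individual summary metrics, K-means
    clustering of round-by-round contribution trajectories with elbow-based
    model selection and rule-based profile naming, and the factorial
    statistical tests (Welch t, Fisher exact, two-way ANOVA) used to compare
    treatments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    car,
    jsonlite,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
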