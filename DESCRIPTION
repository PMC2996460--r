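Package: structbandit
Title: Structure Learning in Two-Armed Bandit Tasks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Bayesian reinforcement-learning models of structure learning in
    two-armed Bernoulli bandit tasks. Implements conjugate belief updating over
    reward probabilities together with a posterior over whether the two options'
    rewards are coupled (one option's success probability is the complement of
    the other's) or independent; optimal action selection under that joint
    uncertainty by belief-state dynamic programming; fixed-structure baselines
    (Gittins-index policy for independent rewards, myopic policy for coupled
    rewards); a model-free Q-learning baseline with soft-max choice and
    prediction-rate fitting; a simulator of the block/task/trial experimental
    design with geometric stopping; and trial-level behavioral analyses
    (diagnostic trials, under-/over-exploration, task-learning trials,
    prediction rates with exact binomial comparisons, coupling-belief choice
    curves and evidence-by-confidence choice surfaces).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
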