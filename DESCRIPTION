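Package: twostepgaze
Title: Two-Stage Decision Task Simulation, Hybrid Reinforcement-Learning
    Model Fitting and Gaze Analysis
Version: 0.1.0
Authors@R:
    person("Analysis", "Pipeline", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for studying model-based versus model-free learning in
    the two-stage (two-step) Markov decision task with eye tracking.
    Generates task sessions with per-trial transition probabilities and
    drifting reward probabilities, simulates hybrid SARSA(lambda) /
    model-based agents (including a colour-cue extension in which explicit
    transition-probability cues are weighted separately), fits the hybrid
    model to choice data by multistart maximum likelihood, computes
    stay-probability tables and stay regressions, processes raw gaze
    samples into cleaned region-of-interest dwells, and produces fully
    synthetic studies (choices plus gaze streams) with known ground truth
    for end-to-end pipeline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    optparse
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
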