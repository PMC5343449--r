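Package: normknockout
Title: Norm Knockout Experiments for the Evolution of Cooperation under
    Indirect Reciprocity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Agent-based simulation of the giving game under indirect
    reciprocity with private reputations. Agents carry one of the sixteen
    binary assessment norms (including Shunning, Stern Judging, Image
    Scoring and Simple Standing), update Good/Bad images of every other
    agent under perception and implementation errors, and evolve their
    norms by a genetic algorithm with squared-payoff roulette selection,
    uniform crossover and per-locus mutation. Implements the norm knockout
    method: a chosen norm is excluded from the population for the whole
    run, and the resulting terminal cooperation classifies norms as
    indispensable for the evolution of cooperation. Includes observables
    for cooperation ratio, norm census and majority-norm transitions,
    experiment presets with reproducible seeding, trajectory
    serialization, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
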