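Package: habitnet
Title: Behavioral-Network Simulation of Habit Formation under Free-Operant
    Reinforcement Schedules
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates habit formation as a structural change in a behavioral
    network. An agent learns transition values between responses by tabular
    temporal-difference learning (Q-learning or SARSA) under free-operant
    reinforcement schedules (fixed/variable ratio, variable interval, variable
    time, tandem and concurrent arrangements); an unweighted network over the
    responses is then generated by softmax edge sampling from the learned
    values, and behavior is simulated as reward-proportional goal choice
    followed by shortest-path traversal. Habit is quantified as resistance to
    reward devaluation (persistence of the operant response after its goal
    value is set to zero), together with the network statistics that explain
    it: operant degree, betweenness centrality, and average path length.
    Includes end-to-end experiment drivers for hypothetical-value sweeps,
    schedule comparisons (VR vs yoked VI, choice vs no-choice), and tandem
    schedule orderings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    igraph,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite,
    yaml,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'RcppExports.R'
    'experiments.R'
    'habitnet-package.R'
    'network.R'
    'qlearning.R'
    'schedules.R'
    'traversal.R'
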