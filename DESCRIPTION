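Package: pdmfeedback
Title: Value-Updating and Boundary-Updating Accounts of Feedback in Perceptual Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation, fitting and comparison of two accounts of how trial-to-trial
    corrective feedback shapes binary perceptual classification: a belief-based
    reinforcement-learning agent that updates choice values by confidence-weighted
    reward prediction errors, and a Bayesian boundary-updating agent (BMBU) that
    treats feedback as evidence about the class boundary of the stimulus
    distribution. Includes the ring-classification task simulator with stochastic
    feedback from a virtual criterion, episode-conditioned psychometric (PSE)
    history-effect analysis with bootstrap, unbiased simulation-based likelihood
    estimation by inverse binomial sampling, multistart derivative-free fitting,
    AICc model evidence, random-effects group Bayesian model selection with
    protected exceedance probabilities, and model/parameter recovery analyses.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    lhs,
    yaml
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
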