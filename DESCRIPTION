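Package: coachrl
Title: Reinforcement Learning for Allocating Scarce Human Feedback in
    Chatbot-Based Smoking Cessation Support
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study when a human coach should send feedback messages
    between sessions of a chatbot-based smoking-cessation intervention. The
    package generates synthetic person-session cohorts with micro-randomized
    feedback assignment, builds interaction samples and abstracts state
    features by iterative Q-value differences, estimates a finite Markov
    decision process (reward and transition functions) from the samples,
    solves it with Gauss-Seidel value iteration under feedback costs, extends
    the model with multi-principle ethical rewards (first-come-first-served,
    sickest-first, priority, autonomy) tuned to a fixed daily feedback
    capacity, simulates a live application with turnover, and fits Bayesian
    random-intercept models for direct, delayed, and dose effects of feedback
    on effort and return likelihood.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    rjags,
    coda,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
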