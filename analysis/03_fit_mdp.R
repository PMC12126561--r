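#!/usr/bin/env Rscript
# Stage 3: estimate the reward and transition functions of the base MDP
# (gamma = 0.85) from the abstracted samples and solve it for the 0.001-
# optimal policy with Gauss-Seidel value iteration.

suppressPackageStartupMessages(library(coachrl))

samples <- read.csv("results/samples.csv",
                    colClasses = c(state = "character",
                                   state_next = "character"))
spec <- read_abstraction_spec("results/abstraction.json")

mdp <- fit_mdp(samples, spec)
write_mdp(mdp, "results/mdp.json")
cat(sprintf("MDP over %d states; sample mean effort %.3f\n",
            length(mdp$states), mdp$mean_effort))

sol <- gauss_seidel_value_iteration(mdp)
cat(sprintf("value iteration converged in %d sweeps\n", sol$iterations))
fb <- feedback_states(sol$policy)
cat(sprintf("cost-free optimal policy gives feedback in %d of %d states\n",
            length(fb), length(mdp$states)))
cat("no-feedback states:", paste(setdiff(mdp$states, fb), collapse = ", "),
    "\n")

jsonlite::write_json(
  list(policy = as.list(sol$policy), V = as.list(round(sol$V, 6))),
  "results/base_policy.json", auto_unbox = TRUE, digits = NA)
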