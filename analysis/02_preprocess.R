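#!/usr/bin/env Rscript
# Stage 2: build interaction samples from the cohort, impute remaining
# feature gaps with population medians, and select the three abstracted base
# state features by iterative Q-value differences (3 x 2 x 2 = 12 states).

suppressPackageStartupMessages(library(coachrl))

cohort <- read.csv("results/cohort.csv")
samples <- build_interaction_samples(cohort)
cat(sprintf("%d interaction samples (consecutive attended session pairs)\n",
            nrow(samples)))

samples <- impute_missing_features(samples)
cat(sprintf("imputed %d missing feature values\n",
            sum(attr(samples, "imputations"))))

spec <- select_base_features(samples)
cat("selected features:", paste(spec$features, collapse = ", "), "\n")
cat("base state space:", paste(spec$schedule, collapse = " x "), "=",
    length(spec$state_labels), "states\n")

samples <- abstract_states(samples, spec)
write.csv(samples, "results/samples.csv", row.names = FALSE)
write_abstraction_spec(spec, "results/abstraction.json")
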