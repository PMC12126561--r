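#!/usr/bin/env Rscript
# Stage 1: generate the synthetic study cohort and the post-questionnaire
# principle-point allocations.
#
# The cohort emulates the longitudinal micro-randomized design: 679 persons,
# up to five chatbot sessions, a 20% feedback chance per between-session gap,
# effort responses around 5.74 (SD 2.75), a delayed feedback effect of +0.39
# effort points (+0.29 return-likelihood points), and a 13% per-session
# dropout hazard.

suppressPackageStartupMessages(library(coachrl))

out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

cfg <- cohort_config(n_persons = 679, seed = 42)
cohort <- generate_cohort(cfg)
write.csv(cohort, file.path(out_dir, "cohort.csv"), row.names = FALSE)
yaml::write_yaml(cfg[setdiff(names(cfg), "feature_spec")],
                 file.path(out_dir, "cohort_config.yaml"))

points <- generate_principle_points(449, default_principle_means(),
                                    concentration = 30, seed = 43)
write.csv(points, file.path(out_dir, "principle_points.csv"),
          row.names = FALSE)

cat(sprintf("cohort: %d person-sessions from %d persons\n",
            nrow(cohort), length(unique(cohort$person_id))))
cat(sprintf("mean effort %.2f (SD %.2f); feedback in %.1f%% of gaps\n",
            mean(cohort$effort, na.rm = TRUE),
            sd(cohort$effort, na.rm = TRUE),
            100 * mean(cohort$feedback, na.rm = TRUE)))
cat(sprintf("principle points: %d respondents x %d principles, rows sum to 100\n",
            nrow(points), ncol(points)))
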