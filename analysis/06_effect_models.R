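#!/usr/bin/env Rscript
# Stage 6: Bayesian random-intercept models for the short-term effects of
# human feedback on effort and return likelihood: direct (feedback in the
# last gap), delayed (any earlier feedback), and dose (number of earlier
# messages) effects.

suppressPackageStartupMessages(library(coachrl))

samples <- read.csv("results/samples.csv",
                    colClasses = c(state = "character",
                                   state_next = "character"))

fits <- list(
  direct_effort   = fit_direct_effect(samples, "effort", seed = 101),
  direct_return   = fit_direct_effect(samples, "return_likelihood", seed = 102),
  delayed_effort  = fit_delayed_effect(samples, "effort", seed = 103),
  delayed_return  = fit_delayed_effect(samples, "return_likelihood", seed = 104),
  dose_effort     = fit_dose_effect(samples, "effort", seed = 105),
  dose_return     = fit_dose_effect(samples, "return_likelihood", seed = 106)
)

tab <- do.call(rbind, lapply(names(fits), function(nm) {
  e <- fits[[nm]]
  data.frame(model = nm, outcome = e$outcome, effect = e$effect,
             b = round(e$b, 3), hdi_lo = round(e$hdi[1], 3),
             hdi_hi = round(e$hdi[2], 3),
             p_positive = round(e$p_positive, 4),
             cohens_d = round(e$cohens_d, 3), n_samples = e$n_samples)
}))
write.csv(tab, "results/effect_estimates.csv", row.names = FALSE)

cat("posterior summaries (b, 95% HDI, P(b>0), d):\n")
for (e in fits) print(e)
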