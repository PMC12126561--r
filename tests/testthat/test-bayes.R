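test_that("posterior summaries behave on degenerate and analytic draws", {
  s <- summarize_posterior(rep(1, 2000), rep(1.5, 2000))
  expect_equal(s$hdi, c(1, 1))
  expect_equal(s$p_positive, 1)
  set.seed(2)
  sym <- rnorm(4000)
  s2 <- summarize_posterior(sym, rep(1, 4000))
  expect_lt(abs(s2$p_positive - 0.5), 0.03)
  # printed (b, d) pairs imply d = b / residual SD
  set.seed(3)
  b <- rnorm(20000, 0.39, 0.11)
  s3 <- summarize_posterior(b, rep(1.56, 20000))
  expect_equal(s3$cohens_d, 0.25, tolerance = 0.01)
  expect_lt(abs(s3$b - 0.39), 0.005)
  expect_error(summarize_posterior(rnorm(500), rep(1, 500)), "1000")
})

test_that("the HDI is the narrowest interval at the requested mass", {
  set.seed(5)
  x <- c(rnorm(5000), rnorm(1000, 8))   # skewed mixture
  s <- summarize_posterior(x, rep(1, 6000))
  covered <- mean(x >= s$hdi[1] & x <= s$hdi[2])
  expect_gte(covered, 0.949)
  q <- unname(stats::quantile(x, c(0.025, 0.975)))
  expect_lte(diff(s$hdi), q[2] - q[1] + 1e-9)
})

test_that("a null generator yields an equivocal posterior", {
  cfg <- cohort_config(n_persons = 500, direct_effort_effect = 0,
                       delayed_effort_effect = 0, direct_return_effect = 0,
                       delayed_return_effect = 0, seed = 14)
  s <- impute_missing_features(build_interaction_samples(generate_cohort(cfg)))
  est <- fit_direct_effect(s, "effort", seed = 10)
  expect_gte(est$p_positive, 0.3)
  expect_lte(est$p_positive, 0.7)
  expect_true(est$hdi[1] <= est$b && est$b <= est$hdi[2])
})

test_that("HDI width shrinks with the sample size", {
  width <- function(n, seed) {
    cfg <- cohort_config(n_persons = n, seed = seed)
    s <- impute_missing_features(
      build_interaction_samples(generate_cohort(cfg)))
    est <- fit_delayed_effect(s, "effort", seed = 20)
    diff(est$hdi)
  }
  expect_lt(width(1000, 8), width(200, 8))
})

test_that("degenerate inputs are refused rather than silently estimated", {
  coh <- toy_cohort(4, 3)
  s <- build_interaction_samples(coh)
  expect_error(fit_direct_effect(s, "effort", seed = 1), "zero variance")
  s$effort <- seq_len(nrow(s))
  expect_error(fit_direct_effect(s, "effort", seed = 1), "constant")
  expect_error(fit_delayed_effect(s, "effort", seed = 1), "constant")
  expect_error(fit_dose_effect(s, "effort", seed = 1), "constant")
})

test_that("a capped dose is flagged as collinear", {
  coh <- toy_cohort(30, 4)
  set.seed(4)
  # at most one feedback message per person: count equals the indicator
  for (p in 1:30) {
    gap <- sample(1:2, 1)
    coh$feedback[coh$person_id == p & coh$session == gap] <-
      as.integer(runif(1) < 0.6)
  }
  coh$effort <- ifelse(coh$session > 1,
                       pmin(pmax(round(rnorm(nrow(coh), 5, 2)), 0), 10),
                       NA)
  s <- build_interaction_samples(coh)
  expect_warning(fit_dose_effect(s, "effort", seed = 2, n_adapt = 200,
                                 n_burn = 200, n_iter = 600),
                 "collinear")
})

test_that("posterior sign probability is invariant to affine rescaling", {
  cfg <- cohort_config(n_persons = 300, seed = 17)
  s <- impute_missing_features(build_interaction_samples(generate_cohort(cfg)))
  e1 <- fit_delayed_effect(s, "effort", seed = 30)
  s2 <- s
  s2$effort <- 2 * s$effort + 3
  e2 <- fit_delayed_effect(s2, "effort", seed = 30)
  expect_lt(abs(e1$p_positive - e2$p_positive), 0.05)
  expect_lt(abs(e2$b - 2 * e1$b), 0.1)
})
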