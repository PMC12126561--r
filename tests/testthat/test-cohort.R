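test_that("generation is deterministic given the seed", {
  cfg <- cohort_config(n_persons = 50, seed = 11)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))
})

test_that("generated values respect their declared ranges", {
  coh <- generate_cohort(cohort_config(n_persons = 200, seed = 3))
  expect_true(all(coh$effort >= 0 & coh$effort <= 10, na.rm = TRUE))
  expect_true(all(coh$effort == round(coh$effort), na.rm = TRUE))
  expect_true(all(coh$return_likelihood >= -5 & coh$return_likelihood <= 5,
                  na.rm = TRUE))
  expect_true(all(coh$importance >= 0 & coh$importance <= 10))
  expect_true(all(coh$appreciation >= -10 & coh$appreciation <= 10))
  expect_true(all(coh$priority_level %in% 0:2))
  # feedback flag only defined between consecutive attended sessions
  last_attended <- tapply(coh$session, coh$person_id, max)
  is_last <- coh$session == last_attended[as.character(coh$person_id)]
  expect_true(all(is.na(coh$feedback[is_last])))
  expect_true(all(!is.na(coh$feedback[!is_last])))
})

test_that("complete follow-up yields (sessions - 1) pairs per person", {
  coh <- generate_cohort(cohort_config(n_persons = 10, n_sessions = 5,
                                       per_session_dropout = 0, seed = 1))
  expect_equal(nrow(coh), 50)
  expect_equal(nrow(build_interaction_samples(coh)), 40)
})

test_that("null configuration shows no feedback effect beyond MC noise", {
  cfg <- cohort_config(n_persons = 500, per_session_dropout = 0,
                       direct_effort_effect = 0, delayed_effort_effect = 0,
                       direct_return_effect = 0, delayed_return_effect = 0,
                       seed = 5)
  s <- build_interaction_samples(generate_cohort(cfg))
  g1 <- s$effort[s$action == 1]
  g0 <- s$effort[s$action == 0]
  se <- sqrt(stats::var(g1) / length(g1) + stats::var(g0) / length(g0))
  expect_lt(abs(mean(g1) - mean(g0)), 3 * se)
})

test_that("delayed effort effect is recovered as a group difference", {
  d <- 0.5
  cfg <- cohort_config(n_persons = 2000, per_session_dropout = 0,
                       direct_effort_effect = 0, delayed_effort_effect = d,
                       seed = 9)
  s <- build_interaction_samples(generate_cohort(cfg))
  g1 <- s$effort[s$any_past_feedback == 1]
  g0 <- s$effort[s$any_past_feedback == 0]
  se <- sqrt(stats::var(g1) / length(g1) + stats::var(g0) / length(g0))
  expect_lt(abs((mean(g1) - mean(g0)) - d), 3 * se)
})

test_that("per-session retention matches the dropout hazard", {
  p_drop <- 0.13
  coh <- generate_cohort(cohort_config(n_persons = 2000, seed = 21))
  att <- table(coh$session)
  for (t in 1:4) {
    n_t <- att[[as.character(t)]]
    kept <- att[[as.character(t + 1)]] / n_t
    se <- sqrt(p_drop * (1 - p_drop) / n_t)
    expect_lt(abs(kept - (1 - p_drop)), 3 * se)
  }
})

test_that("invalid configurations name the offending field", {
  expect_error(cohort_config(10, p_feedback = 1.2), "p_feedback")
  expect_error(cohort_config(10, per_session_dropout = -0.1),
               "per_session_dropout")
  expect_error(cohort_config(10, n_sessions = 1), "n_sessions")
  expect_error(cohort_config(10, effort_mean = 12), "effort_mean")
})

test_that("principle point allocations sum to 100 and match their means", {
  w <- default_principle_means()
  pts <- generate_principle_points(2000, w, concentration = 30, seed = 4)
  expect_true(all(rowSums(pts) == 100))
  expect_true(all(pts >= 0))
  props <- colMeans(pts) / 100
  se <- apply(pts / 100, 2, stats::sd) / sqrt(nrow(pts))
  expect_true(all(abs(props - w) < 2 * se + 1e-12))
})

test_that("infinite concentration degenerates to the mean allocation", {
  w <- rep(1 / 11, 11)
  pts <- generate_principle_points(300, w, concentration = 1e9, seed = 2)
  expect_true(all(abs(colMeans(pts) - 100 / 11) < 0.5))
})

test_that("malformed principle weights are rejected", {
  expect_error(generate_principle_points(5, c(0.5, 0.4)), "sum to 1")
})
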