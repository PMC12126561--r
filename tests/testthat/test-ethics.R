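test_that("auxiliary rewards are rescaled and gated on allocation", {
  fit <- fitted_synthetic()
  st <- sprintf("%s-p2-t0", fit$mdp$states[1])
  expect_equal(auxiliary_reward("fcfs", st, 1, fit$mdp), 0)
  expect_equal(auxiliary_reward("priority", st, 1, fit$mdp), 1)
  for (p in c("fcfs", "sickest", "priority", "autonomy"))
    expect_equal(auxiliary_reward(p, st, 0, fit$mdp), 0)
  st2 <- sprintf("%s-p0-t2", fit$mdp$states[1])
  expect_equal(auxiliary_reward("fcfs", st2, 1, fit$mdp), 1)
  expect_error(auxiliary_reward("lottery", st, 1, fit$mdp), "unknown")
})

test_that("sickest-first scores span [0, 1] across base states", {
  fit <- fitted_synthetic()
  aux <- vapply(fit$mdp$states, function(b)
    auxiliary_reward("sickest", list(base = b, priority = 0, tsf = 0), 1,
                     fit$mdp), numeric(1))
  expect_equal(min(aux), 0)
  expect_equal(max(aux), 1)
})

test_that("the extended model has 108 factorizing states", {
  fit <- fitted_synthetic()
  m <- build_extended_mdp(fit$mdp, smoker_preferred_weights(), cost = 0.05,
                          appreciation_digit = fit$app_digit)
  ext <- attr(m, "ext")
  expect_equal(nrow(ext), 108)
  expect_true(all(abs(apply(m$T, c(1, 2), sum) - 1) < 1e-9))
  # feedback resets the clock: successors of a = 1 all have tsf 0
  reached <- m$T[, 2, ] > 0
  tsf_next <- ext$tsf[col(reached)][reached]
  expect_true(all(tsf_next == 0))
  # no feedback at the cap: tsf stays 2 and priority never changes
  at_cap <- which(ext$tsf == 2)
  for (e in at_cap[1:6]) {
    to <- which(m$T[e, 1, ] > 0)
    expect_true(all(ext$tsf[to] == 2))
    expect_true(all(ext$priority[to] == ext$priority[e]))
  }
})

test_that("prognosis-only weights collapse to the base policy", {
  fit <- fitted_synthetic()
  cost <- 0.02
  base_pol <- gauss_seidel_value_iteration(
    with_feedback_cost(fit$mdp, cost))$policy
  m <- build_extended_mdp(fit$mdp, ethical_weights(1, 0, 0, 0, 0), cost,
                          appreciation_digit = fit$app_digit)
  ext_pol <- gauss_seidel_value_iteration(m)$policy
  ext <- attr(m, "ext")
  expect_equal(unname(ext_pol), unname(base_pol[ext$base]))
})

test_that("unnormalized weights are rejected", {
  expect_error(ethical_weights(0.5, 0.2, 0.2, 0.2, 0.2), "sum to 1")
  fit <- fitted_synthetic()
  expect_error(build_extended_mdp(fit$mdp, c(0.5, 0.2, 0.2, 0.2, 0.2)),
               "sum to 1")
})

test_that("capacity tuning hits the target and is monotone in cost", {
  fit <- fitted_synthetic()
  lac <- live_app_config()
  tuned <- tune_cost_to_capacity(fit$mdp, ethical_weights(1, 0, 0, 0, 0),
                                 fit$init, lac,
                                 appreciation_digit = fit$app_digit)
  expect_lte(abs(tuned$fraction - 0.35), 0.01)
  # a clearly higher cost allocates no more feedback
  m2 <- build_extended_mdp(fit$mdp, ethical_weights(1, 0, 0, 0, 0),
                           tuned$cost + 0.05,
                           appreciation_digit = fit$app_digit)
  pol2 <- gauss_seidel_value_iteration(m2)$policy
  ss2 <- live_app_steady_state(pol2, m2, fit$init, lac)
  expect_lte(ss2$feedback_fraction, tuned$fraction + 1e-9)
})

test_that("single-session apps replace every person every day", {
  fit <- fitted_synthetic()
  lac <- live_app_config(n_spots = 30, n_sessions = 1, dropout = 0, seed = 5)
  ext <- extended_state_table(fit$mdp$states)
  pol <- setNames(rep(0L, 108), ext$label)
  log <- simulate_live_application(pol, fit$mdp, lac, fit$init, n_days = 5)
  expect_equal(anyDuplicated(log$person_id), 0)
})

test_that("never-feedback logs only action 0 and ratchets the clock", {
  fit <- fitted_synthetic()
  lac <- live_app_config(n_spots = 40, n_sessions = 20, dropout = 0, seed = 6)
  ext <- extended_state_table(fit$mdp$states)
  pol <- setNames(rep(0L, 108), ext$label)
  log <- simulate_live_application(pol, fit$mdp, lac, fit$init, n_days = 8)
  expect_true(all(log$action == 0))
  expect_true(all(log$time_since_feedback[log$day >= 3] == 2))
})

test_that("subgroup shares sum to 100 and track occupancy under random allocation", {
  fit <- fitted_synthetic()
  lac <- live_app_config(n_spots = 166, seed = 9)
  ext <- extended_state_table(fit$mdp$states)
  pol <- setNames(rep(0.5, 108), ext$label)
  log <- simulate_live_application(pol, fit$mdp, lac, fit$init, n_days = 200)
  rep <- subgroup_allocation_report(log, fit$mdp,
                                    appreciation_digit = fit$app_digit)
  sums <- tapply(rep$share, rep$criterion, sum)
  expect_true(all(abs(sums - 100) < 0.01))
  # allocation is state-independent, so shares approximate occupancy shares
  occ_p <- 100 * table(factor(log$priority, 0:2)) / nrow(log)
  got <- rep$share[rep$criterion == "priority"]
  expect_true(all(abs(got - as.numeric(occ_p)) < 2))
  expect_error(subgroup_allocation_report(log[log$action == 0, ], fit$mdp),
               "no feedback")
})

test_that("a priority-gated policy concentrates its share", {
  fit <- fitted_synthetic()
  ext <- extended_state_table(fit$mdp$states)
  pol <- setNames(as.integer(ext$priority == 2), ext$label)
  lac <- live_app_config(n_spots = 60, seed = 3)
  log <- simulate_live_application(pol, fit$mdp, lac, fit$init, n_days = 50)
  rep <- subgroup_allocation_report(log, fit$mdp,
                                    appreciation_digit = fit$app_digit)
  expect_equal(rep$share[rep$criterion == "priority" & rep$level == "high"],
               100)
})
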