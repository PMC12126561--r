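test_that("the effort-reward map anchors the mean at 0.5 and the endpoints", {
  expect_equal(effort_to_reward(5.74, 5.74), 0.5)
  expect_equal(effort_to_reward(0, 5.74), 0)
  expect_equal(effort_to_reward(10, 5.74), 1)
  expect_equal(effort_to_reward(2.87, 5.74), 0.25)
  expect_error(effort_to_reward(-1, 5.74), "0, 10")
  expect_error(effort_to_reward(11, 5.74), "0, 10")
})

test_that("the effort-reward map is strictly increasing and continuous", {
  e <- seq(0, 10, by = 0.01)
  r <- effort_to_reward(e, 5.74)
  expect_true(all(diff(r) > 0))
  eps <- 1e-9
  expect_equal(effort_to_reward(5.74 - eps, 5.74), 0.5, tolerance = 1e-6)
  expect_equal(effort_to_reward(5.74 + eps, 5.74), 0.5, tolerance = 1e-6)
})

test_that("reward inversion is exact", {
  expect_equal(reward_to_effort(0.5, 5.74), 5.74)
  expect_equal(reward_to_effort(1, 5.74), 10)
  expect_equal(reward_to_effort(0.66, 5.74), 7.1032)
  e <- seq(0, 10, by = 0.05)
  expect_equal(reward_to_effort(effort_to_reward(e, 5.74), 5.74), e,
               tolerance = 1e-9)
  expect_error(reward_to_effort(1.2, 5.74), "0, 1")
})

test_that("the feedback cost applies only to the feedback action", {
  expect_equal(cost_adjusted_reward(0.6, 0, 0.07), 0.6)
  expect_equal(cost_adjusted_reward(0.6, 1, 0.07), 0.53)
  expect_equal(cost_adjusted_reward(0.0, 1, 0.18), -0.18)
  expect_error(cost_adjusted_reward(0.5, 1, -0.1), "non-negative")
})

test_that("reward estimation averages per cell with a grand-mean fallback", {
  s <- data.frame(state = c("0", "0"), state_next = c("0", "0"),
                  action = c(1L, 1L), effort = c(5.74, 5.74))
  est <- estimate_reward_function(s, states = c("0", "1"),
                                  mean_effort = 5.74)
  expect_equal(est$R["0", "a1"], 0.5)
  # two samples in one cell average; empty cells carry the grand mean
  s2 <- data.frame(state = c("0", "0"), action = c(0L, 0L),
                   effort = c(reward_to_effort(0.2, 5.74),
                              reward_to_effort(0.6, 5.74)))
  est2 <- estimate_reward_function(s2, states = c("0", "1"),
                                   mean_effort = 5.74)
  expect_equal(est2$R["0", "a0"], 0.4)
  expect_equal(est2$R["1", "a1"], 0.4)        # grand mean fallback
  expect_equal(est2$support["1", "a1"], 0L)   # flagged as unsupported
  expect_error(estimate_reward_function(s2[0, ]), "no samples")
})

test_that("transition estimation applies additive smoothing", {
  s <- data.frame(state = rep("A", 4), action = 1L,
                  state_next = c("B", "B", "B", "A"))
  est <- estimate_transition_function(s, states = c("A", "B"), lambda = 1)
  expect_equal(est$T["A", "a1", ], c(A = 2 / 6, B = 4 / 6))
  # zero-support rows are uniform
  expect_equal(unname(est$T["B", "a0", ]), c(0.5, 0.5))
  est12 <- estimate_transition_function(
    data.frame(state = "001", action = 0L, state_next = "001"),
    states = sprintf("%03d", 0:11), lambda = 1)
  expect_equal(unname(est12$T["000", "a1", ]), rep(1 / 12, 12))
  # unsmoothed estimation is the raw frequency
  est0 <- estimate_transition_function(
    data.frame(state = rep("A", 5), action = 1L, state_next = rep("B", 5)),
    states = c("A", "B"), lambda = 0)
  expect_equal(unname(est0$T["A", "a1", ]), c(0, 1))
})

test_that("transition rows are stochastic and smoothing pulls to uniform", {
  fit <- fitted_synthetic()
  expect_true(all(abs(apply(fit$mdp$T, c(1, 2), sum) - 1) < 1e-9))
  tv_to_uniform <- function(lambda) {
    est <- estimate_transition_function(fit$samples,
                                        states = fit$mdp$states,
                                        lambda = lambda)
    mean(apply(est$T, c(1, 2), function(p) sum(abs(p - 1 / length(p))) / 2))
  }
  tv <- vapply(c(0, 1, 5, 50), tv_to_uniform, numeric(1))
  expect_true(all(diff(tv) < 1e-12))
})

test_that("MDP models survive a JSON round trip", {
  fit <- fitted_synthetic()
  path <- tempfile(fileext = ".json")
  write_mdp(fit$mdp, path)
  m2 <- read_mdp(path)
  expect_equal(m2$states, fit$mdp$states)
  expect_equal(unname(m2$R), unname(fit$mdp$R), tolerance = 1e-12)
  expect_equal(unname(m2$T), unname(fit$mdp$T), tolerance = 1e-12)
})
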