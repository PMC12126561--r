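# shared fixtures, built once per test run

.fixture_env <- new.env(parent = emptyenv())

# the study-scale synthetic cohort fitted end-to-end (679 persons, seed 42)
fitted_synthetic <- function() {
  if (is.null(.fixture_env$fit)) {
    cfg <- cohort_config(n_persons = 679, seed = 42)
    cohort <- generate_cohort(cfg)
    samples <- impute_missing_features(build_interaction_samples(cohort))
    spec <- select_base_features(samples)
    samples <- abstract_states(samples, spec)
    mdp <- fit_mdp(samples, spec)
    .fixture_env$fit <- list(
      config = cfg, cohort = cohort, samples = samples, spec = spec,
      mdp = mdp,
      init = initial_state_distribution(samples, mdp$states),
      app_digit = match("appreciation", spec$features)
    )
  }
  .fixture_env$fit
}

# hand-built cohort table: persons x sessions with full control over gaps
toy_cohort <- function(n_persons = 1, n_sessions = 5) {
  g <- expand.grid(person_id = seq_len(n_persons),
                   session = seq_len(n_sessions))
  g <- g[order(g$person_id, g$session), ]
  g$priority_level <- 0L
  g$importance <- 5
  g$self_efficacy <- 5
  g$appreciation <- 0
  g$energy <- 5
  g$activity_difficulty <- 5
  g$feedback <- ifelse(g$session < n_sessions, 0L, NA_integer_)
  g$effort <- ifelse(g$session > 1, 5, NA_real_)
  g$return_likelihood <- ifelse(g$session > 1, 1, NA_real_)
  rownames(g) <- NULL
  g
}

# tiny deterministic MDP: 2 states, feedback moves mass to the good state
chain_mdp <- function(gamma = 0.85) {
  T <- array(0, c(2, 2, 2))
  T[1, 1, ] <- c(0.9, 0.1); T[1, 2, ] <- c(0.4, 0.6)
  T[2, 1, ] <- c(0.5, 0.5); T[2, 2, ] <- c(0.1, 0.9)
  R <- rbind(c(0.3, 0.3), c(0.8, 0.8))
  new_mdp(c("0", "1"), R, T, gamma = gamma, mean_effort = 5.74)
}
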