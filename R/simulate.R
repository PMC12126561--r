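#' Initial base-state distribution from first-session samples
#'
#' Empirical distribution of the abstracted state at the study's first
#' session, used to seed the population simulations.
#'
#' @param samples abstracted samples (columns `session`, `state`).
#' @param states full state-label vector.
#' @param session which session to condition on (default 1).
#' @return named probability vector with attribute `provenance`.
#' @export
initial_state_distribution <- function(samples, states, session = 1L) {
  st <- samples$state[samples$session == session]
  if (!length(st)) stop("no samples in the requested session", call. = FALSE)
  p <- table(factor(st, levels = states))
  p <- as.numeric(p) / sum(p)
  structure(stats::setNames(p, states), provenance = "first-session empirical")
}

#' State-independent action mixture
#'
#' Represents a stochastic policy that takes action 1 with probability `w1`
#' in every state (e.g., the theoretical half-half policy).
#'
#' @param w1 probability of giving feedback.
#' @return an `action_mixture` weight vector `c(1 - w1, w1)`.
#' @export
action_mixture <- function(w1) {
  stopifnot(w1 >= 0, w1 <= 1)
  structure(c(1 - w1, w1), class = "action_mixture")
}

# per-state probability of action 1; deterministic 0/1 policies and global
# action mixtures are special cases
policy_prob <- function(mdp, policy) {
  n <- length(mdp$states)
  p <- if (inherits(policy, "action_mixture")) rep(policy[2], n)
       else as.numeric(policy)
  if (length(p) != n)
    stop("policy and MDP state sets differ", call. = FALSE)
  if (any(p < 0 | p > 1))
    stop("policy entries must be probabilities in [0, 1]", call. = FALSE)
  p
}

policy_kernel <- function(mdp, policy) {
  n <- length(mdp$states)
  p <- policy_prob(mdp, policy)
  T0 <- mdp$T[, 1, , drop = TRUE]
  T1 <- mdp$T[, 2, , drop = TRUE]
  if (n == 1L) { T0 <- matrix(T0, 1, 1); T1 <- matrix(T1, 1, 1) }
  (1 - p) * T0 + p * T1
}

policy_reward <- function(mdp, policy) {
  p <- policy_prob(mdp, policy)
  (1 - p) * mdp$R[, 1L] + p * mdp$R[, 2L]
}

#' Propagate a population distribution one step
#'
#' `mass'(s') = sum_s mass(s) T(s, a(s), s')`; for an action mixture the
#' kernel is the weighted average of the two action kernels.
#'
#' @param dist named probability vector over the MDP's states.
#' @param policy 0/1 vector over states, or a length-2 mixture weight vector
#'   `c(w0, w1)`.
#' @param mdp an `mdp_model`.
#' @return next distribution (named, sums to 1).
#' @export
propagate <- function(dist, policy, mdp) {
  if (length(dist) != length(mdp$states))
    stop("distribution and MDP state sets differ", call. = FALSE)
  M <- policy_kernel(mdp, policy)
  stats::setNames(as.vector(dist %*% M), mdp$states)
}

simulate_policy_trajectory <- function(mdp, policy, init, horizon, label) {
  rew <- policy_reward(mdp, policy)
  frac_vec <- policy_prob(mdp, policy)
  M <- policy_kernel(mdp, policy)
  dist <- init
  mr <- numeric(horizon)
  ff <- numeric(horizon)
  for (t in seq_len(horizon)) {
    mr[t] <- sum(dist * rew)
    ff[t] <- sum(dist * frac_vec)
    dist <- stats::setNames(as.vector(dist %*% M), mdp$states)
  }
  out <- data.frame(policy = label, t = seq_len(horizon), mean_reward = mr,
                    feedback_fraction = ff, stringsAsFactors = FALSE)
  attr(out, "final_dist") <- dist
  out
}

#' Compare the four reference feedback policies
#'
#' Propagates the initial population through the fitted MDP under (1) the
#' cost-free optimal policy, (2) always giving feedback, (3) a theoretical
#' average policy taking each action half the time, and (4) never giving
#' feedback, reporting the mean base reward per activity assignment and the
#' feedback fraction at each step (exact expectation propagation, no
#' sampling noise).
#'
#' @param mdp fitted `mdp_model` (base, cost-free rewards).
#' @param init_dist initial state distribution.
#' @param horizon number of time steps (default 100).
#' @return tidy data frame (`policy`, `t`, `mean_reward`,
#'   `feedback_fraction`); the optimal policy itself is in attribute
#'   `optimal_policy`.
#' @export
simulate_policies <- function(mdp, init_dist, horizon = 100L) {
  if (horizon < 1L) stop("horizon must be >= 1", call. = FALSE)
  n <- length(mdp$states)
  opt <- gauss_seidel_value_iteration(mdp)$policy
  res <- rbind(
    simulate_policy_trajectory(mdp, opt, init_dist, horizon, "optimal"),
    simulate_policy_trajectory(mdp, stats::setNames(rep(1L, n), mdp$states),
                               init_dist, horizon, "always"),
    simulate_policy_trajectory(mdp, action_mixture(0.5), init_dist, horizon,
                               "half"),
    simulate_policy_trajectory(mdp, stats::setNames(rep(0L, n), mdp$states),
                               init_dist, horizon, "never")
  )
  attr(res, "optimal_policy") <- opt
  res
}

#' Seeded Monte-Carlo rollout of a policy (cross-check mode)
#'
#' Samples individual trajectories instead of propagating the distribution
#' exactly; used to validate the expectation propagation within Monte-Carlo
#' error.
#'
#' @param mdp an `mdp_model`.
#' @param policy 0/1 vector over states.
#' @param init_dist initial distribution.
#' @param horizon steps.
#' @param n_people number of simulated people.
#' @param seed integer seed.
#' @return data frame (`t`, `mean_reward`).
#' @export
simulate_policy_mc <- function(mdp, policy, init_dist, horizon = 100L,
                               n_people = 1000L, seed = 1L) {
  set.seed(as.integer(seed))
  n <- length(mdp$states)
  a <- as.integer(policy) + 1L
  rew <- mdp$R[cbind(seq_len(n), a)]
  s <- sample.int(n, n_people, replace = TRUE, prob = init_dist)
  out <- data.frame(t = seq_len(horizon), mean_reward = NA_real_)
  for (t in seq_len(horizon)) {
    out$mean_reward[t] <- mean(rew[s])
    s <- vapply(s, function(si)
      sample.int(n, 1L, prob = mdp$T[si, a[si], ]), integer(1))
  }
  out
}

#' Sweep the human feedback cost
#'
#' For each cost, plans on the cost-adjusted reward, then simulates the
#' resulting policy reporting the base (cost-free) reward. Emits the
#' policy-by-state feedback matrix and the per-cost trajectories.
#'
#' @param mdp fitted base `mdp_model`.
#' @param costs numeric vector of costs; the default grid spans the range in
#'   which the optimal policy sheds feedback states one by one on the study's
#'   fitted model.
#' @param init_dist initial state distribution.
#' @param horizon steps (default 100).
#' @return list with `policies` (0/1 matrix costs x states), `trajectories`
#'   (tidy data frame with a `cost` column), and `n_feedback_states`.
#' @export
cost_sweep <- function(mdp, costs = c(0, 0.02, 0.03, 0.05, 0.055, 0.07, 0.09,
                                      0.1, 0.102, 0.12, 0.18),
                       init_dist, horizon = 100L) {
  if (any(costs < 0)) stop("costs must be non-negative", call. = FALSE)
  n <- length(mdp$states)
  pol_mat <- matrix(0L, length(costs), n,
                    dimnames = list(sprintf("c=%g", costs), mdp$states))
  traj <- NULL
  for (i in seq_along(costs)) {
    sol <- gauss_seidel_value_iteration(with_feedback_cost(mdp, costs[i]))
    pol_mat[i, ] <- sol$policy
    tr <- simulate_policy_trajectory(mdp, sol$policy, init_dist, horizon,
                                     sprintf("pi*,%g", costs[i]))
    tr$cost <- costs[i]
    traj <- rbind(traj, tr)
  }
  list(policies = pol_mat, trajectories = traj,
       n_feedback_states = rowSums(pol_mat))
}
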