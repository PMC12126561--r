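#' Map an effort response to a base reward
#'
#' Piecewise-linear map from the 0-10 effort scale to a reward in \[0, 1\]:
#' an effort equal to the population mean effort earns 0.5, and efforts
#' below (above) the mean are spaced evenly over \[0, 0.5\] (\[0.5, 1\]):
#' \deqn{r = e / (2\bar e)} for \eqn{e < \bar e},
#' \deqn{r = 1 - (10 - e) / (2 (10 - \bar e))} for \eqn{e > \bar e},
#' and 0.5 otherwise.
#'
#' @param e effort response(s) in \[0, 10\].
#' @param mean_effort population mean effort \eqn{\bar e} in (0, 10).
#' @return reward(s) in \[0, 1\].
#' @export
effort_to_reward <- function(e, mean_effort) {
  if (any(is.na(e)) || any(e < 0) || any(e > 10))
    stop("effort must lie in [0, 10]", call. = FALSE)
  if (mean_effort <= 0 || mean_effort >= 10)
    stop("mean_effort must lie in (0, 10)", call. = FALSE)
  ifelse(e < mean_effort, e / (2 * mean_effort),
         ifelse(e > mean_effort, 1 - (10 - e) / (2 * (10 - mean_effort)), 0.5))
}

#' Invert the effort-to-reward map
#'
#' @param r reward(s) in \[0, 1\].
#' @param mean_effort population mean effort in (0, 10).
#' @return effort value(s) in \[0, 10\]; 0.5 maps back to `mean_effort`.
#' @export
reward_to_effort <- function(r, mean_effort) {
  if (any(is.na(r)) || any(r < 0) || any(r > 1))
    stop("reward must lie in [0, 1]", call. = FALSE)
  ifelse(r < 0.5, r * 2 * mean_effort,
         ifelse(r > 0.5, 10 - (1 - r) * 2 * (10 - mean_effort), mean_effort))
}

#' Subtract the human feedback cost from a reward
#'
#' The cost applies only when feedback is given (`a = 1`); the result is not
#' clipped and may be negative.
#'
#' @param r base reward(s).
#' @param a action(s), 0 (no feedback) or 1 (feedback).
#' @param c feedback cost, `c >= 0`.
#' @return cost-adjusted reward(s).
#' @export
cost_adjusted_reward <- function(r, a, c) {
  if (c < 0) stop("cost must be non-negative", call. = FALSE)
  if (!all(a %in% c(0, 1))) stop("action must be 0 or 1", call. = FALSE)
  r - c * (a == 1)
}

#' Construct a finite two-action MDP model
#'
#' @param states character vector of state labels (kept in sorted order).
#' @param R numeric matrix `|S| x 2` of expected rewards (columns: a = 0, 1).
#' @param T numeric array `|S| x 2 x |S|` of transition probabilities.
#' @param gamma discount factor in \[0, 1).
#' @param mean_effort population mean effort stored with the model so reward
#'   inversions reuse the same constant.
#' @param support optional list of per-cell sample counts.
#' @return an `mdp_model`.
#' @export
new_mdp <- function(states, R, T, gamma = 0.85, mean_effort = NA_real_,
                    support = NULL) {
  n <- length(states)
  stopifnot(nrow(R) == n, ncol(R) == 2L, all(dim(T) == c(n, 2L, n)))
  if (gamma < 0 || gamma >= 1) stop("gamma must lie in [0, 1)", call. = FALSE)
  rs <- apply(T, c(1, 2), sum)
  if (any(abs(rs - 1) > 1e-9))
    stop("each T(s, a, .) must sum to 1", call. = FALSE)
  dimnames(R) <- list(states, c("a0", "a1"))
  dimnames(T) <- list(states, c("a0", "a1"), states)
  structure(list(states = states, R = R, T = T, gamma = gamma,
                 mean_effort = mean_effort, support = support),
            class = "mdp_model")
}

#' @export
print.mdp_model <- function(x, ...) {
  cat("MDP model:", length(x$states), "states, 2 actions, gamma =", x$gamma,
      "\n")
  if (!is.na(x$mean_effort))
    cat("mean effort:", round(x$mean_effort, 3), "\n")
  invisible(x)
}

#' Estimate the reward function from abstracted interaction samples
#'
#' `R(s, a)` is the mean of [effort_to_reward()] over the samples landing in
#' that state-action cell; cells with no samples fall back to the grand mean
#' reward and are flagged in the support counts.
#'
#' @param samples table with columns `state`, `action`, `effort`.
#' @param states full state-label vector.
#' @param mean_effort optional; defaults to the sample mean effort.
#' @return list with matrix `R`, matrix `support` (sample counts), and
#'   `mean_effort`.
#' @export
estimate_reward_function <- function(samples, states = sort(unique(samples$state)),
                                     mean_effort = NULL) {
  if (!nrow(samples)) stop("no samples to estimate rewards from", call. = FALSE)
  if (is.null(mean_effort)) mean_effort <- mean(samples$effort)
  r <- effort_to_reward(samples$effort, mean_effort)
  grand <- mean(r)
  R <- matrix(grand, length(states), 2L, dimnames = list(states, c("a0", "a1")))
  support <- matrix(0L, length(states), 2L,
                    dimnames = list(states, c("a0", "a1")))
  for (a in 0:1) {
    sel <- samples$action == a
    if (!any(sel)) next
    m <- tapply(r[sel], factor(samples$state[sel], levels = states), mean)
    cnt <- tapply(rep(1L, sum(sel)), factor(samples$state[sel], levels = states),
                  sum)
    has <- !is.na(m)
    R[has, a + 1L] <- m[has]
    support[has, a + 1L] <- cnt[has]
  }
  list(R = R, support = support, mean_effort = mean_effort)
}

#' Estimate the transition function from abstracted interaction samples
#'
#' Additive smoothing with pseudo-count `lambda`:
#' `T(s, a, s') = (count(s, a, s') + lambda) / (count(s, a) + lambda |S|)`.
#' With `lambda = 0`, zero-support `(s, a)` rows become uniform.
#'
#' @param samples table with columns `state`, `action`, `state_next`.
#' @param states full state-label vector.
#' @param lambda pseudo-count (default 1).
#' @return list with array `T` (`|S| x 2 x |S|`) and matrix `support`.
#' @export
estimate_transition_function <- function(samples,
                                         states = sort(unique(c(samples$state,
                                                                samples$state_next))),
                                         lambda = 1) {
  if (!nrow(samples)) stop("no samples to estimate transitions from",
                           call. = FALSE)
  n <- length(states)
  T <- array(0, c(n, 2L, n), dimnames = list(states, c("a0", "a1"), states))
  support <- matrix(0L, n, 2L, dimnames = list(states, c("a0", "a1")))
  for (a in 0:1) {
    sel <- samples$action == a
    cnt <- table(factor(samples$state[sel], levels = states),
                 factor(samples$state_next[sel], levels = states))
    row_tot <- rowSums(cnt)
    support[, a + 1L] <- row_tot
    for (si in seq_len(n)) {
      if (row_tot[si] + lambda * n > 0) {
        T[si, a + 1L, ] <- (cnt[si, ] + lambda) / (row_tot[si] + lambda * n)
      } else {
        T[si, a + 1L, ] <- 1 / n
      }
    }
  }
  # unsmoothed zero-support rows: uniform
  for (a in 1:2) for (si in seq_len(n))
    if (support[si, a] == 0 && lambda == 0) T[si, a, ] <- 1 / n
  list(T = T, support = support)
}

fit_mdp_from_states <- function(state, state_next, action, effort, states,
                                gamma = 0.85, lambda = 1, mean_effort = NULL) {
  s <- data.frame(state = state, state_next = state_next, action = action,
                  effort = effort, stringsAsFactors = FALSE)
  rew <- estimate_reward_function(s, states, mean_effort)
  tr <- estimate_transition_function(s, states, lambda)
  new_mdp(states, rew$R, tr$T, gamma = gamma, mean_effort = rew$mean_effort,
          support = list(R = rew$support, T = tr$support))
}

#' Fit the base MDP from abstracted interaction samples
#'
#' Estimates the reward and transition functions over the abstraction spec's
#' state space and wraps them as an [new_mdp()] model.
#'
#' @param samples abstracted samples (columns `state`, `state_next`,
#'   `action`, `effort`).
#' @param spec an `abstraction_spec` (supplies the full state-label set), or
#'   `NULL` to use the labels observed in the samples.
#' @param gamma discount factor.
#' @param lambda transition pseudo-count.
#' @param mean_effort optional fixed population mean effort.
#' @return an `mdp_model`.
#' @export
fit_mdp <- function(samples, spec = NULL, gamma = 0.85, lambda = 1,
                    mean_effort = NULL) {
  states <- if (!is.null(spec)) spec$state_labels else
    sort(unique(c(samples$state, samples$state_next)))
  fit_mdp_from_states(samples$state, samples$state_next, samples$action,
                      samples$effort, states, gamma, lambda, mean_effort)
}

#' Apply a feedback cost to an MDP's reward function
#'
#' @param mdp an `mdp_model`.
#' @param cost feedback cost `c >= 0` subtracted from `R(s, 1)`.
#' @return a new `mdp_model` with the cost-adjusted rewards.
#' @export
with_feedback_cost <- function(mdp, cost) {
  R <- mdp$R
  R[, 2L] <- cost_adjusted_reward(R[, 2L], 1, cost)
  structure(list(states = mdp$states, R = R, T = mdp$T, gamma = mdp$gamma,
                 mean_effort = mdp$mean_effort, support = mdp$support),
            class = "mdp_model")
}

#' Serialize an MDP model to JSON
#' @param mdp an `mdp_model`.
#' @param path file path.
#' @export
write_mdp <- function(mdp, path) {
  jsonlite::write_json(
    list(states = mdp$states, R = unname(mdp$R),
         T0 = unname(mdp$T[, 1, , drop = TRUE]),
         T1 = unname(mdp$T[, 2, , drop = TRUE]),
         gamma = mdp$gamma, mean_effort = mdp$mean_effort),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an MDP model from JSON
#' @param path file path.
#' @export
read_mdp <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  n <- length(x$states)
  T <- array(0, c(n, 2L, n))
  T[, 1, ] <- as.matrix(x$T0)
  T[, 2, ] <- as.matrix(x$T1)
  new_mdp(x$states, as.matrix(x$R), T, gamma = x$gamma,
          mean_effort = x$mean_effort)
}
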