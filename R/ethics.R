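#' Weights over the five allocation-principle rewards
#'
#' @param prognosis,fcfs,sickest,priority,autonomy non-negative weights for
#'   the base (benefit-maximizing) reward and the four auxiliary rewards.
#' @param normalize if `TRUE`, rescale to sum to 1; otherwise the weights
#'   must already sum to 1 within 1e-9.
#' @return named `ethical_weights` vector.
#' @export
ethical_weights <- function(prognosis, fcfs, sickest, priority, autonomy,
                            normalize = FALSE) {
  w <- c(prognosis = prognosis, fcfs = fcfs, sickest = sickest,
         priority = priority, autonomy = autonomy)
  if (any(w < 0)) stop("weights must be non-negative", call. = FALSE)
  if (normalize) w <- w / sum(w)
  if (abs(sum(w) - 1) > 1e-9)
    stop("weights must sum to 1 (use normalize = TRUE to rescale)",
         call. = FALSE)
  structure(w, class = "ethical_weights")
}

#' Smoker-preferred principle weights
#'
#' Aggregate mean weights that post-questionnaire respondents assigned to
#' the five reward groups: prognosis 30.82%, first-come-first-served 22.18%,
#' sickest-first 25.34%, priority 13.04%, autonomy 8.62%.
#'
#' @return an [ethical_weights()] vector.
#' @export
smoker_preferred_weights <- function() {
  ethical_weights(0.3082, 0.2218, 0.2534, 0.1304, 0.0862)
}

#' Extended state table
#'
#' Base states crossed with the two allocation features: a fixed individual
#' priority level (0-2) and the time since the last human feedback (0-2,
#' capped). 12 base states give 108 extended states.
#'
#' @param base_states character vector of base-state labels.
#' @return data frame (`label`, `base`, `priority`, `tsf`), ordered by base
#'   label, then priority, then time since feedback.
#' @export
extended_state_table <- function(base_states) {
  g <- expand.grid(tsf = 0:2, priority = 0:2, base = sort(base_states),
                   stringsAsFactors = FALSE)
  g <- g[, c("base", "priority", "tsf")]
  g$label <- sprintf("%s-p%d-t%d", g$base, g$priority, g$tsf)
  g[, c("label", "base", "priority", "tsf")]
}

parse_extended_state <- function(label) {
  parts <- regmatches(label, regexec("^(.+)-p([0-9])-t([0-9])$", label))[[1]]
  if (length(parts) != 4L) stop("not an extended state label: ", label,
                                call. = FALSE)
  list(base = parts[2], priority = as.integer(parts[3]),
       tsf = as.integer(parts[4]))
}

sickness_scores <- function(base_mdp) {
  r0 <- base_mdp$R[, 1L]
  rng <- diff(range(r0))
  if (rng == 0) return(stats::setNames(rep(0, length(r0)), base_mdp$states))
  (max(r0) - r0) / rng
}

appreciation_level <- function(base_label, appreciation_digit = 3L) {
  as.integer(substr(base_label, appreciation_digit, appreciation_digit))
}

#' Auxiliary reward of an allocation principle
#'
#' Each principle's measure is rescaled to \[0, 1\] as
#' `(aux - aux_min) / (aux_max - aux_min)` and granted only when feedback is
#' given (`a = 1`): `fcfs` uses the time since the last feedback (0-2),
#' `sickest` the shortfall of the no-feedback reward `R(s, 0)` rescaled over
#' its observed range across base states, `priority` the fixed priority
#' level (0-2), and `autonomy` the feedback-appreciation level of the base
#' state (0 or 1).
#'
#' @param principle one of `"fcfs"`, `"sickest"`, `"priority"`, `"autonomy"`.
#' @param extended_state an extended-state label (see
#'   [extended_state_table()]) or a list with `base`, `priority`, `tsf`.
#' @param action 0 or 1.
#' @param base_mdp the fitted base `mdp_model` (needed for `sickest`).
#' @param appreciation_digit which digit of the base label encodes
#'   appreciation (default 3, the study's feature order).
#' @return auxiliary reward in \[0, 1\].
#' @export
auxiliary_reward <- function(principle, extended_state, action, base_mdp,
                             appreciation_digit = 3L) {
  if (!principle %in% c("fcfs", "sickest", "priority", "autonomy"))
    stop("unknown principle: ", principle, call. = FALSE)
  if (action == 0) return(0)
  st <- if (is.character(extended_state)) parse_extended_state(extended_state)
        else extended_state
  switch(principle,
    fcfs = st$tsf / 2,
    sickest = unname(sickness_scores(base_mdp)[st$base]),
    priority = st$priority / 2,
    autonomy = appreciation_level(st$base, appreciation_digit)
  )
}

extended_transitions <- function(base_mdp, ext) {
  n_b <- length(base_mdp$states)
  n_e <- nrow(ext)
  base_idx <- match(ext$base, base_mdp$states)
  T <- array(0, c(n_e, 2L, n_e), dimnames = list(ext$label, c("a0", "a1"),
                                                 ext$label))
  # destination index lookup by (base, priority, tsf)
  idx <- function(b, p, t) {
    which(ext$base == b & ext$priority == p & ext$tsf == t)
  }
  dest <- array(0L, c(n_b, 3L, 3L))
  for (bi in seq_len(n_b)) for (p in 0:2) for (t in 0:2)
    dest[bi, p + 1L, t + 1L] <- idx(base_mdp$states[bi], p, t)
  for (e in seq_len(n_e)) {
    p <- ext$priority[e]
    for (a in 0:1) {
      t_next <- if (a == 1L) 0L else min(ext$tsf[e] + 1L, 2L)
      to <- dest[, p + 1L, t_next + 1L]
      T[e, a + 1L, to] <- base_mdp$T[base_idx[e], a + 1L, ]
    }
  }
  T
}

extended_rewards <- function(base_mdp, ext, weights, cost,
                             appreciation_digit = 3L) {
  base_idx <- match(ext$base, base_mdp$states)
  sick <- sickness_scores(base_mdp)[base_idx]
  appr <- appreciation_level(ext$base, appreciation_digit)
  R <- matrix(0, nrow(ext), 2L)
  for (a in 0:1) {
    # cost may be negative here: when a capacity target binds from below,
    # the tuned cost acts as a (signed) Lagrange multiplier on feedback
    prog <- base_mdp$R[cbind(base_idx, a + 1L)] - cost * (a == 1L)
    aux <- if (a == 1L) {
      weights["fcfs"] * ext$tsf / 2 + weights["sickest"] * sick +
        weights["priority"] * ext$priority / 2 + weights["autonomy"] * appr
    } else 0
    R[, a + 1L] <- weights["prognosis"] * prog + aux
  }
  R
}

#' Build the ethically extended MDP
#'
#' Extends the base model over priority level and time since feedback: base
#' features follow the base transition function, priority is static, and the
#' time since feedback resets to 0 on feedback and otherwise increments
#' (capped at 2). The reward is the weighted sum of the cost-adjusted base
#' (prognosis) reward and the four allocation-gated auxiliary rewards.
#'
#' @param base_mdp fitted base `mdp_model`.
#' @param weights an [ethical_weights()] vector.
#' @param cost feedback cost applied to the base reward.
#' @param appreciation_digit digit of the base label encoding appreciation.
#' @return an `mdp_model` over the extended states.
#' @export
build_extended_mdp <- function(base_mdp, weights, cost = 0,
                               appreciation_digit = 3L) {
  if (!inherits(weights, "ethical_weights")) {
    if (abs(sum(weights) - 1) > 1e-9)
      stop("weights must sum to 1", call. = FALSE)
    weights <- do.call(ethical_weights, as.list(unname(weights)))
  }
  ext <- extended_state_table(base_mdp$states)
  T <- extended_transitions(base_mdp, ext)
  R <- extended_rewards(base_mdp, ext, weights, cost, appreciation_digit)
  m <- new_mdp(ext$label, R, T, gamma = base_mdp$gamma,
               mean_effort = base_mdp$mean_effort)
  attr(m, "ext") <- ext
  m
}

#' Live-application configuration
#'
#' Defaults describe the envisioned deployment: 166 concurrent spots, up to
#' nine sessions per person, a 15% dropout chance after each session, and a
#' human coach able to reach about 35% of active people per day.
#'
#' @param n_spots concurrent application spots.
#' @param n_sessions sessions to completion.
#' @param dropout per-session dropout probability.
#' @param capacity target daily feedback fraction.
#' @param seed integer seed for the agent-based simulation.
#' @return a `live_app_config` list.
#' @export
live_app_config <- function(n_spots = 166L, n_sessions = 9L, dropout = 0.15,
                            capacity = 0.35, seed = 42L) {
  if (dropout < 0 || dropout > 1) stop("dropout must lie in [0, 1]",
                                       call. = FALSE)
  if (capacity <= 0 || capacity > 1) stop("capacity must lie in (0, 1]",
                                          call. = FALSE)
  structure(list(n_spots = as.integer(n_spots),
                 n_sessions = as.integer(n_sessions), dropout = dropout,
                 capacity = capacity, seed = as.integer(seed)),
            class = "live_app_config")
}

init_extended_distribution <- function(ext, init_base) {
  p <- init_base[ext$base] * (1 / 3) * (ext$tsf == 0L)
  stats::setNames(as.numeric(p), ext$label)
}

#' Steady-state population of the live application under a policy
#'
#' Exact expectation propagation of the turnover process: each day every
#' active person has a session; afterwards they drop out with the configured
#' probability or complete after the final session, and vacated spots are
#' refilled from the first-session base-state distribution with uniform
#' priority levels and time since feedback 0. The population state is the
#' joint distribution over (extended state, session age); iteration runs to
#' a fixed point.
#'
#' @param policy named 0/1 vector over the extended states.
#' @param ext_mdp extended `mdp_model` (from [build_extended_mdp()]).
#' @param init_base named distribution over base states.
#' @param config a [live_app_config()].
#' @param tol convergence tolerance on the L1 change per iteration.
#' @param max_iter iteration cap.
#' @return list with `dist` (steady distribution over extended states),
#'   `feedback_fraction`, and `iterations`.
#' @export
live_app_steady_state <- function(policy, ext_mdp, init_base, config,
                                  tol = 1e-10, max_iter = 5000L) {
  ext <- attr(ext_mdp, "ext")
  n_e <- nrow(ext)
  S <- config$n_sessions
  M_pol <- policy_kernel(ext_mdp, policy[ext$label])
  init_ext <- init_extended_distribution(ext, init_base)
  cont <- c(rep(1 - config$dropout, S - 1L), 0)
  # mass over (extended state, session age)
  M <- matrix(0, n_e, S)
  M[, 1L] <- init_ext
  for (it in seq_len(max_iter)) {
    M_new <- matrix(0, n_e, S)
    for (g in seq_len(S - 1L)) {
      flow <- cont[g] * M[, g]
      if (sum(flow) > 0) M_new[, g + 1L] <- as.vector(flow %*% M_pol)
    }
    exited <- 1 - sum(M_new)
    M_new[, 1L] <- M_new[, 1L] + exited * init_ext
    delta <- sum(abs(M_new - M))
    M <- M_new
    if (delta < tol) break
  }
  dist <- stats::setNames(rowSums(M), ext$label)
  frac <- sum(dist * policy_prob(ext_mdp, policy[ext$label]))
  list(dist = dist, feedback_fraction = frac, iterations = it)
}

#' Tune the feedback cost to a daily capacity
#'
#' Bisects the feedback cost so that the optimal policy of the ethically
#' extended model allocates feedback to the target fraction of active people
#' in the live application's steady state. Because deterministic optimal
#' policies change at discrete cost thresholds, the achieved fraction is a
#' step function of the cost; when no deterministic policy lands within
#' `tol` of the target, the two policies bracketing it (both epsilon-optimal
#' at the threshold cost) are blended by randomizing the action in the
#' states where they disagree — the standard device for meeting a capacity
#' constraint exactly in a constrained MDP — and the blend weight is bisected
#' until the steady-state fraction matches the target.
#'
#' @param base_mdp fitted base `mdp_model`.
#' @param weights an [ethical_weights()] vector.
#' @param init_base named distribution over base states.
#' @param config a [live_app_config()].
#' @param target target feedback fraction (defaults to the config capacity).
#' @param tol acceptable deviation from the target.
#' @param appreciation_digit digit of the base label encoding appreciation.
#' @param max_iter bisection iterations.
#' @return list with `cost`, `fraction`, `policy`, `ext_mdp`, `steady`.
#' @export
tune_cost_to_capacity <- function(base_mdp, weights, init_base, config,
                                  target = config$capacity, tol = 0.01,
                                  appreciation_digit = 3L, max_iter = 30L) {
  if (target <= 0 || target >= 1) stop("target must lie in (0, 1)",
                                       call. = FALSE)
  eval_cost <- function(cost) {
    m <- build_extended_mdp(base_mdp, weights, cost, appreciation_digit)
    sol <- gauss_seidel_value_iteration(m)
    ss <- live_app_steady_state(sol$policy, m, init_base, config)
    list(cost = cost, fraction = ss$feedback_fraction, policy = sol$policy,
         ext_mdp = m, steady = ss)
  }
  lo <- 0; hi <- 1
  r_lo <- eval_cost(lo); r_hi <- eval_cost(hi)
  # if the capacity target is not reachable with a non-negative cost (the
  # auxiliary rewards can make withholding attractive even for free
  # feedback), extend the bracket to negative costs: the tuned cost is the
  # signed multiplier of the capacity constraint
  while (r_lo$fraction < target - tol && lo > -1) {
    lo <- lo - 0.25
    r_lo <- eval_cost(lo)
  }
  best <- if (abs(r_lo$fraction - target) <= abs(r_hi$fraction - target))
    r_lo else r_hi
  if (r_lo$fraction < target - tol)
    stop(sprintf(paste0("target fraction %.3f unreachable: cost %.2f ",
                        "allocates only %.3f"), target, lo, r_lo$fraction),
         call. = FALSE)
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    r <- eval_cost(mid)
    if (abs(r$fraction - target) < abs(best$fraction - target)) best <- r
    if (r$fraction > target) { lo <- mid; r_lo <- r } else { hi <- mid; r_hi <- r }
  }
  if (abs(best$fraction - target) <= tol) return(best)
  # no deterministic policy within tol: randomize the boundary states
  # between the bracketing epsilon-optimal policies
  pol_hi <- r_lo$policy   # allocates more (fraction >= target)
  pol_lo <- r_hi$policy   # allocates less (fraction <= target)
  m <- r_lo$ext_mdp
  blend <- function(theta) {
    pol <- (1 - theta) * pol_lo + theta * pol_hi
    ss <- live_app_steady_state(pol, m, init_base, config)
    list(cost = (r_lo$cost + r_hi$cost) / 2, fraction = ss$feedback_fraction,
         policy = pol, ext_mdp = m, steady = ss, mix_theta = theta)
  }
  t_lo <- 0; t_hi <- 1
  r <- blend(0.5)
  for (i in seq_len(max_iter)) {
    if (abs(r$fraction - target) < abs(best$fraction - target)) best <- r
    if (abs(best$fraction - target) <= tol / 2) break
    if (r$fraction > target) t_hi <- r$mix_theta else t_lo <- r$mix_theta
    r <- blend((t_lo + t_hi) / 2)
  }
  if (abs(best$fraction - target) > tol)
    stop(sprintf(paste0("no policy in the cost family reaches fraction ",
                        "%.3f within %.3f; closest was %.3f at cost %.4f"),
                 target, tol, best$fraction, best$cost), call. = FALSE)
  best
}

#' Agent-based simulation of the live application
#'
#' Seeded discrete simulation of the configured number of concurrent spots:
#' each day every person's base state transitions according to the base
#' model given the policy's action, the time since feedback resets or
#' ratchets, people drop out after each session with the configured
#' probability or complete after the final session, and vacated spots are
#' refilled from the first-session distribution with uniform priority
#' levels.
#'
#' @param policy named 0/1 vector over extended-state labels.
#' @param base_mdp fitted base `mdp_model`.
#' @param config a [live_app_config()].
#' @param init_base named distribution over base states.
#' @param n_days days to simulate.
#' @return allocation log: data frame (`day`, `person_id`, `state`,
#'   `priority`, `time_since_feedback`, `action`).
#' @export
simulate_live_application <- function(policy, base_mdp, config, init_base,
                                      n_days = 200L) {
  stopifnot(inherits(config, "live_app_config"))
  set.seed(config$seed)
  n_b <- length(base_mdp$states)
  n <- config$n_spots
  draw_base <- function(k) sample.int(n_b, k, replace = TRUE, prob = init_base)
  base_i <- draw_base(n)
  prio <- sample(0:2, n, replace = TRUE)
  tsf <- rep(0L, n)
  age <- rep(1L, n)
  pid <- seq_len(n)
  next_pid <- n + 1L
  logs <- vector("list", n_days)
  for (day in seq_len(n_days)) {
    labels <- sprintf("%s-p%d-t%d", base_mdp$states[base_i], prio, tsf)
    p_act <- unname(policy[labels])
    act <- ifelse(p_act %in% c(0, 1), p_act,
                  as.numeric(stats::runif(n) < p_act))
    act <- as.integer(act)
    logs[[day]] <- data.frame(day = day, person_id = pid,
                              state = base_mdp$states[base_i],
                              priority = prio, time_since_feedback = tsf,
                              action = act, stringsAsFactors = FALSE)
    # transition attended people
    new_base <- vapply(seq_len(n), function(j)
      sample.int(n_b, 1L, prob = base_mdp$T[base_i[j], act[j] + 1L, ]),
      integer(1))
    new_tsf <- ifelse(act == 1L, 0L, pmin(tsf + 1L, 2L))
    leave <- age >= config$n_sessions | stats::runif(n) < config$dropout
    k <- sum(leave)
    base_i <- new_base; tsf <- as.integer(new_tsf); age <- age + 1L
    if (k) {
      base_i[leave] <- draw_base(k)
      prio[leave] <- sample(0:2, k, replace = TRUE)
      tsf[leave] <- 0L
      age[leave] <- 1L
      pid[leave] <- seq.int(next_pid, length.out = k)
      next_pid <- next_pid + k
    }
  }
  do.call(rbind, logs)
}

criterion_classes <- function(base_mdp, occupancy, q_base = NULL,
                              appreciation_digit = 3L) {
  if (is.null(q_base)) q_base <- gauss_seidel_value_iteration(base_mdp)$Q
  qgap <- q_base[, 2L] - q_base[, 1L]
  sick <- sickness_scores(base_mdp)
  wq <- function(values, w, probs) {
    o <- order(values)
    cw <- cumsum(w[o]) / sum(w)
    vapply(probs, function(p) values[o][which(cw >= p - 1e-12)[1L]], numeric(1))
  }
  cls3 <- function(values) {
    cuts <- wq(values, occupancy, c(1 / 3, 2 / 3))
    as.integer(values > cuts[1]) + as.integer(values > cuts[2])
  }
  data.frame(
    base = base_mdp$states,
    prognosis = cls3(qgap),
    sickest = cls3(sick),
    autonomy = appreciation_level(base_mdp$states, appreciation_digit),
    stringsAsFactors = FALSE
  )
}

subgroup_shares_worker <- function(rows, base_mdp, q_base = NULL,
                                   appreciation_digit = 3L) {
  occ <- tapply(rows$w_occ, factor(rows$base, levels = base_mdp$states), sum)
  occ[is.na(occ)] <- 0
  cls <- criterion_classes(base_mdp, as.numeric(occ), q_base,
                           appreciation_digit)
  rows <- merge(rows, cls, by = "base", sort = FALSE)
  total <- sum(rows$w_alloc)
  if (total <= 0) stop("no feedback events to report on", call. = FALSE)
  share <- function(class_vec, n_levels) {
    s <- vapply(0:(n_levels - 1L), function(l)
      100 * sum(rows$w_alloc[class_vec == l]) / total, numeric(1))
    names(s) <- c("low", "medium", "high")[seq_len(n_levels)]
    if (n_levels == 2L) names(s) <- c("low", "high")
    s
  }
  res <- list(
    prognosis = share(rows$prognosis, 3L),
    fcfs = share(rows$tsf, 3L),
    sickest = share(rows$sickest, 3L),
    autonomy = share(rows$autonomy, 2L),
    priority = share(rows$priority, 3L)
  )
  do.call(rbind, lapply(names(res), function(cr)
    data.frame(criterion = cr, level = names(res[[cr]]),
               share = as.numeric(res[[cr]]), stringsAsFactors = FALSE)))
}

#' Feedback shares by smoker subgroup from an allocation log
#'
#' Classifies every feedback event by the five allocation criteria and
#' reports the percentage of feedback each subgroup received. Prognosis
#' subgroups are occupancy-weighted tertiles of the base-model Q-value gain
#' `Q*(s,1) - Q*(s,0)`; sickest-first subgroups are tertiles of the
#' no-feedback reward shortfall (high = sickest); first-come-first-served
#' uses the time since the last feedback; autonomy the two appreciation
#' levels; priority the three priority levels. Shares sum to 100% per
#' criterion.
#'
#' @param log allocation log from [simulate_live_application()].
#' @param base_mdp fitted base `mdp_model`.
#' @param q_base optional precomputed base Q matrix.
#' @param appreciation_digit digit of the base label encoding appreciation.
#' @return data frame (`criterion`, `level`, `share`).
#' @export
subgroup_allocation_report <- function(log, base_mdp, q_base = NULL,
                                       appreciation_digit = 3L) {
  if (!nrow(log) || !any(log$action == 1L))
    stop("allocation log contains no feedback events", call. = FALSE)
  rows <- data.frame(base = log$state, priority = log$priority,
                     tsf = log$time_since_feedback,
                     w_occ = 1, w_alloc = as.numeric(log$action == 1L),
                     stringsAsFactors = FALSE)
  subgroup_shares_worker(rows, base_mdp, q_base, appreciation_digit)
}

#' Feedback shares by smoker subgroup from a steady-state distribution
#'
#' Deterministic counterpart of [subgroup_allocation_report()]: allocation
#' weights are the steady-state occupancy of the extended states with
#' feedback action, occupancy weights the full steady-state mass.
#'
#' @param steady_dist named distribution over extended-state labels.
#' @param policy named 0/1 vector over extended-state labels.
#' @param base_mdp fitted base `mdp_model`.
#' @param q_base optional precomputed base Q matrix.
#' @param appreciation_digit digit of the base label encoding appreciation.
#' @return data frame (`criterion`, `level`, `share`).
#' @export
subgroup_shares_steady <- function(steady_dist, policy, base_mdp,
                                   q_base = NULL, appreciation_digit = 3L) {
  info <- lapply(names(steady_dist), parse_extended_state)
  rows <- data.frame(
    base = vapply(info, `[[`, character(1), "base"),
    priority = vapply(info, `[[`, integer(1), "priority"),
    tsf = vapply(info, `[[`, integer(1), "tsf"),
    w_occ = as.numeric(steady_dist),
    w_alloc = as.numeric(steady_dist) *
      as.numeric(unname(policy[names(steady_dist)])),
    stringsAsFactors = FALSE)
  subgroup_shares_worker(rows, base_mdp, q_base, appreciation_digit)
}

#' Compare the six principle-weighted allocation policies
#'
#' Builds and tunes (to the capacity target) the prognosis-only policy, the
#' four two-principle policies pairing prognosis with one auxiliary reward
#' (weights split by the two principles' preference ratio, renormalized),
#' and the all-five policy at the full preference weights, then reports
#' steady-state subgroup feedback shares for each.
#'
#' @param base_mdp fitted base `mdp_model`.
#' @param init_base named distribution over base states.
#' @param config a [live_app_config()].
#' @param weights full five-principle weights (default
#'   [smoker_preferred_weights()]).
#' @param tol capacity tolerance passed to [tune_cost_to_capacity()].
#' @param appreciation_digit digit of the base label encoding appreciation.
#' @return list with `shares` (long data frame with a `policy` column),
#'   `costs`, and `fractions`.
#' @export
compare_principle_policies <- function(base_mdp, init_base, config,
                                       weights = smoker_preferred_weights(),
                                       tol = 0.01, appreciation_digit = 3L) {
  q_base <- gauss_seidel_value_iteration(base_mdp)$Q
  pair_weights <- function(p) {
    w <- c(prognosis = unname(weights["prognosis"]), fcfs = 0, sickest = 0,
           priority = 0, autonomy = 0)
    w[p] <- unname(weights[p])
    do.call(ethical_weights, c(as.list(unname(w)), normalize = TRUE))
  }
  specs <- list(
    prognosis = ethical_weights(1, 0, 0, 0, 0),
    `prognosis+fcfs` = pair_weights("fcfs"),
    `prognosis+sickest` = pair_weights("sickest"),
    `prognosis+autonomy` = pair_weights("autonomy"),
    `prognosis+priority` = pair_weights("priority"),
    `smoker-preferred` = weights
  )
  shares <- NULL
  costs <- fractions <- stats::setNames(numeric(length(specs)), names(specs))
  for (nm in names(specs)) {
    tuned <- tune_cost_to_capacity(base_mdp, specs[[nm]], init_base, config,
                                   tol = tol,
                                   appreciation_digit = appreciation_digit)
    sh <- subgroup_shares_steady(tuned$steady$dist, tuned$policy, base_mdp,
                                 q_base, appreciation_digit)
    sh$policy <- nm
    shares <- rbind(shares, sh)
    costs[nm] <- tuned$cost
    fractions[nm] <- tuned$fraction
  }
  list(shares = shares, costs = costs, fractions = fractions)
}
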