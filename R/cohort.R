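#' Configuration for the synthetic person-session cohort generator
#'
#' Builds a validated configuration for [generate_cohort()]. The defaults
#' emulate the micro-randomized study the package re-analyses: up to five
#' chatbot sessions per person, a 20% chance of human feedback in each gap
#' between attended sessions, self-reported effort on a 0-10 scale with
#' population mean 5.74 (SD 2.75), a small direct and a larger delayed
#' positive feedback effect on effort and return likelihood, and a 13%
#' per-session dropout hazard.
#'
#' Effort reported in session *t* refers to the activity assigned in session
#' *t - 1*. Its mean is shifted by `direct_effort_effect` when feedback was
#' received in the immediately preceding gap, by `delayed_effort_effect` when
#' feedback was received in any earlier gap, and by `dose_effort_effect` per
#' earlier feedback message. Return likelihood (-5..5) is handled analogously
#' on its own scale. Both are drawn from a normal, rounded to integers and
#' clipped to their scales.
#'
#' State features (importance, self-efficacy, appreciation, energy, activity
#' difficulty) are discretized normals whose means load on a shared latent
#' person intercept; feedback in the preceding gap additionally shifts the
#' next session's feature means by `feedback_feature_effect` (a state-mediated
#' channel through which feedback influences future engagement).
#'
#' @param n_persons number of persons.
#' @param n_sessions sessions per person before completion (>= 2).
#' @param p_feedback probability of human feedback per between-session gap.
#' @param effort_mean,effort_sd population effort scale (0-10 points).
#' @param direct_effort_effect,delayed_effort_effect,dose_effort_effect
#'   effort shifts (scale points) for last-gap feedback, any earlier
#'   feedback, and per earlier feedback message.
#' @param direct_return_effect,delayed_return_effect,dose_return_effect
#'   analogous shifts for return likelihood.
#' @param return_mean,return_sd return-likelihood scale (-5..5 points).
#' @param per_session_dropout probability of dropping out after each session.
#' @param person_sd SD of the latent person intercept (scale points).
#' @param feature_spec data frame describing the raw state features (columns
#'   `feature`, `mean`, `sd`, `loading`, `fb_effect`, `min`, `max`); defaults
#'   via [default_feature_spec()].
#' @param seed integer seed; every draw is reproducible given it.
#' @return A `cohort_config` list.
#' @export
cohort_config <- function(n_persons,
                          n_sessions = 5L,
                          p_feedback = 0.20,
                          effort_mean = 5.74,
                          effort_sd = 2.75,
                          direct_effort_effect = 0.08,
                          delayed_effort_effect = 0.39,
                          dose_effort_effect = 0,
                          direct_return_effect = 0.03,
                          delayed_return_effect = 0.29,
                          dose_return_effect = 0,
                          return_mean = 1.8,
                          return_sd = 2.7,
                          per_session_dropout = 0.13,
                          person_sd = 1.0,
                          feature_spec = default_feature_spec(),
                          seed = 42L) {
  cfg <- list(
    n_persons = as.integer(n_persons), n_sessions = as.integer(n_sessions),
    p_feedback = p_feedback, effort_mean = effort_mean, effort_sd = effort_sd,
    direct_effort_effect = direct_effort_effect,
    delayed_effort_effect = delayed_effort_effect,
    dose_effort_effect = dose_effort_effect,
    direct_return_effect = direct_return_effect,
    delayed_return_effect = delayed_return_effect,
    dose_return_effect = dose_return_effect,
    return_mean = return_mean, return_sd = return_sd,
    per_session_dropout = per_session_dropout, person_sd = person_sd,
    feature_spec = feature_spec, seed = as.integer(seed)
  )
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
  cfg
}

validate_cohort_config <- function(cfg) {
  chk_prob <- function(name) {
    v <- cfg[[name]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1)
      stop("cohort_config: field '", name, "' must be a probability in [0, 1]",
           call. = FALSE)
  }
  chk_prob("p_feedback")
  chk_prob("per_session_dropout")
  if (cfg$n_persons < 1L)
    stop("cohort_config: field 'n_persons' must be >= 1", call. = FALSE)
  if (cfg$n_sessions < 2L)
    stop("cohort_config: field 'n_sessions' must be >= 2", call. = FALSE)
  if (cfg$effort_mean < 0 || cfg$effort_mean > 10)
    stop("cohort_config: field 'effort_mean' must lie in [0, 10]", call. = FALSE)
  if (cfg$effort_sd <= 0)
    stop("cohort_config: field 'effort_sd' must be positive", call. = FALSE)
  if (cfg$person_sd < 0)
    stop("cohort_config: field 'person_sd' must be non-negative", call. = FALSE)
  fs <- cfg$feature_spec
  need <- c("feature", "mean", "sd", "loading", "fb_effect", "min", "max")
  if (!is.data.frame(fs) || !all(need %in% names(fs)))
    stop("cohort_config: field 'feature_spec' must be a data frame with columns ",
         paste(need, collapse = ", "), call. = FALSE)
  invisible(cfg)
}

#' Default raw state-feature specification
#'
#' Five self-report features measured at every session. Means and SDs are
#' chosen to resemble mid-scale responding with a positively skewed feedback
#' appreciation (median around 6 on -10..10); loadings on the latent person
#' intercept induce the correlation between features and effort; `fb_effect`
#' is the shift in the next session's feature mean after receiving feedback.
#'
#' @return data frame, one row per feature.
#' @export
default_feature_spec <- function() {
  data.frame(
    feature   = c("importance", "self_efficacy", "appreciation", "energy",
                  "activity_difficulty"),
    mean      = c(6.5, 5.5, 4.0, 5.5, 4.0),
    sd        = c(2.0, 2.2, 4.5, 2.0, 2.0),
    loading   = c(0.7, 0.6, 1.2, 0.3, -0.2),
    fb_effect = c(0.5, 0.5, 1.0, 0.0, 0.0),
    min       = c(0, 0, -10, 0, 0),
    max       = c(10, 10, 10, 10, 10),
    stringsAsFactors = FALSE
  )
}

round_clip <- function(x, lo, hi) pmin(pmax(round(x), lo), hi)

#' Generate a synthetic person-session cohort
#'
#' Simulates the longitudinal micro-randomized design: each person attends up
#' to `n_sessions` chatbot sessions, may drop out after each session, and in
#' each gap between consecutive attended sessions has probability
#' `p_feedback` of receiving a human feedback message. Sessions 2 onwards
#' carry the effort spent on the previous activity (0-10) and the likelihood
#' of having returned were the program unpaid (-5..5).
#'
#' @param config a [cohort_config()].
#' @return data frame with one row per attended person-session: `person_id`,
#'   `session`, `priority_level`, `latent_intercept`, the five raw state
#'   features, `feedback` (1 if a feedback message was sent in the gap after
#'   this session; `NA` when there is no following attended session),
#'   `effort` and `return_likelihood` (`NA` in session 1).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  validate_cohort_config(config)
  set.seed(config$seed)
  n <- config$n_persons
  S <- config$n_sessions
  fs <- config$feature_spec
  nf <- nrow(fs)

  u <- stats::rnorm(n, 0, config$person_sd)
  priority <- sample(0:2, n, replace = TRUE)

  # attendance: everyone attends session 1; after each session an attendee
  # drops with per_session_dropout, independently
  attend <- matrix(FALSE, n, S)
  attend[, 1] <- TRUE
  for (t in seq_len(S - 1L)) {
    stay <- stats::runif(n) >= config$per_session_dropout
    attend[, t + 1L] <- attend[, t] & stay
  }

  # feedback in gap t -> t+1 only when both sessions are attended
  fb <- matrix(0L, n, S) # column t = gap after session t; last column unused
  for (t in seq_len(S - 1L)) {
    both <- attend[, t] & attend[, t + 1L]
    fb[both, t] <- as.integer(stats::runif(sum(both)) < config$p_feedback)
  }

  feat <- array(NA_real_, c(n, S, nf), dimnames = list(NULL, NULL, fs$feature))
  effort <- matrix(NA_real_, n, S)
  ret <- matrix(NA_real_, n, S)

  for (t in seq_len(S)) {
    idx <- which(attend[, t])
    if (!length(idx)) next
    fb_last <- if (t > 1L) fb[idx, t - 1L] else rep(0L, length(idx))
    for (k in seq_len(nf)) {
      mu <- fs$mean[k] + fs$loading[k] * u[idx] + fs$fb_effect[k] * fb_last
      feat[idx, t, k] <- round_clip(stats::rnorm(length(idx), mu, fs$sd[k]),
                                    fs$min[k], fs$max[k])
    }
    if (t > 1L) {
      earlier <- if (t > 2L) fb[idx, seq_len(t - 2L), drop = FALSE] else
        matrix(0L, length(idx), 0L)
      n_earlier <- if (ncol(earlier)) rowSums(earlier) else rep(0, length(idx))
      any_earlier <- as.numeric(n_earlier > 0)
      mu_e <- config$effort_mean + u[idx] +
        config$direct_effort_effect * fb_last +
        config$delayed_effort_effect * any_earlier +
        config$dose_effort_effect * n_earlier
      effort[idx, t] <- round_clip(stats::rnorm(length(idx), mu_e,
                                                config$effort_sd), 0, 10)
      mu_r <- config$return_mean + u[idx] +
        config$direct_return_effect * fb_last +
        config$delayed_return_effect * any_earlier +
        config$dose_return_effect * n_earlier
      ret[idx, t] <- round_clip(stats::rnorm(length(idx), mu_r,
                                             config$return_sd), -5, 5)
    }
  }

  rows <- which(attend, arr.ind = TRUE)
  rows <- rows[order(rows[, 1L], rows[, 2L]), , drop = FALSE]
  i <- rows[, 1L]; t <- rows[, 2L]
  fb_out <- ifelse(t < S & attend[cbind(i, pmin(t + 1L, S))], fb[cbind(i, t)],
                   NA_integer_)
  out <- data.frame(
    person_id = i, session = t,
    priority_level = priority[i], latent_intercept = u[i],
    stringsAsFactors = FALSE
  )
  for (k in seq_len(nf)) out[[fs$feature[k]]] <- feat[cbind(i, t, k)]
  out$feedback <- as.integer(fb_out)
  out$effort <- effort[cbind(i, t)]
  out$return_likelihood <- ret[cbind(i, t)]
  out
}

#' Generate 100-point allocations over principle statements
#'
#' Emulates the post-questionnaire task of distributing 100 points across
#' allocation-principle statements with a Dirichlet-multinomial scheme: each
#' respondent's latent preference vector is Dirichlet with mean
#' `mean_weights` and the given concentration, and the 100 points are a
#' multinomial draw from it. Expected point proportions equal `mean_weights`.
#'
#' @param n_persons number of respondents.
#' @param mean_weights vector of mean proportions, must sum to 1.
#' @param concentration Dirichlet concentration (larger = less between-person
#'   variation).
#' @param seed integer seed.
#' @return integer matrix `n_persons` x `length(mean_weights)`, rows sum to 100.
#' @export
generate_principle_points <- function(n_persons, mean_weights,
                                      concentration = 50, seed = 42L) {
  if (abs(sum(mean_weights) - 1) > 1e-6)
    stop("mean_weights must sum to 1", call. = FALSE)
  if (any(mean_weights < 0)) stop("mean_weights must be non-negative", call. = FALSE)
  set.seed(as.integer(seed))
  k <- length(mean_weights)
  out <- matrix(0L, n_persons, k)
  alpha <- concentration * mean_weights
  for (i in seq_len(n_persons)) {
    g <- stats::rgamma(k, shape = alpha, rate = 1)
    # degenerate components (alpha == 0) stay at weight 0
    if (sum(g) == 0) g <- mean_weights
    p <- g / sum(g)
    out[i, ] <- as.integer(stats::rmultinom(1, 100, p))
  }
  colnames(out) <- names(mean_weights)
  out
}

#' Default mean weights for the 11 allocation-principle statements
#'
#' The questionnaire's 11 statements collapse into five reward groups
#' (prognosis; treating people equally; sickest first; individual priority;
#' autonomy) with aggregate mean weights 30.82%, 22.18%, 25.34%, 13.04% and
#' 8.62%. The default splits each group's aggregate weight equally across its
#' member statements.
#'
#' @return named numeric vector of length 11 summing to 1.
#' @export
default_principle_means <- function() {
  groups <- list(
    prognosis = c("prognosis_engagement", "prognosis_health"),
    equal     = c("lottery", "first_come_first_served", "least_feedback_so_far"),
    sickest   = c("sickest_engagement", "sickest_health"),
    priority  = c("youngest_first", "instrumental_value", "reciprocity"),
    autonomy  = c("autonomy")
  )
  agg <- c(prognosis = 0.3082, equal = 0.2218, sickest = 0.2534,
           priority = 0.1304, autonomy = 0.0862)
  w <- unlist(lapply(names(groups), function(g) {
    m <- groups[[g]]
    stats::setNames(rep(agg[[g]] / length(m), length(m)), m)
  }))
  w / sum(w)
}
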