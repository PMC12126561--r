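#' Build interaction samples from a person-session cohort table
#'
#' An interaction sample is one pair of consecutive attended sessions: the
#' state features and feedback action are taken from the first session of the
#' pair, while the reported effort and return likelihood (which refer to the
#' activity assigned in the first session) are taken from the second. A pair
#' is retained only when the second session has non-missing effort, return
#' likelihood, and perceived importance (the first state question).
#'
#' The returned table also carries the feedback history covariates used by
#' the effect models: `any_past_feedback` (feedback in any gap strictly
#' before the pair's gap) and `n_past_feedback` (count of such messages).
#'
#' @param cohort data frame as returned by [generate_cohort()] (columns
#'   `person_id`, `session`, the five raw state features, `feedback`,
#'   `effort`, `return_likelihood`; extra columns are carried through
#'   per-person).
#' @return data frame of samples with feature columns at the first session
#'   (`importance`, ..., `session`) and at the next session (`*_next`),
#'   `action`, `effort`, `return_likelihood`.
#' @export
build_interaction_samples <- function(cohort) {
  features <- c("importance", "self_efficacy", "appreciation", "energy",
                "activity_difficulty")
  need <- c("person_id", "session", features, "feedback", "effort",
            "return_likelihood")
  missing_cols <- setdiff(need, names(cohort))
  if (length(missing_cols))
    stop("cohort table is missing columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)

  cohort <- cohort[order(cohort$person_id, cohort$session), ]
  out <- lapply(split(cohort, cohort$person_id), function(d) {
    if (nrow(d) < 2L) return(NULL)
    # consecutive attended sessions
    i <- which(diff(d$session) == 1L)
    if (!length(i)) return(NULL)
    nxt <- i + 1L
    keep <- !is.na(d$effort[nxt]) & !is.na(d$return_likelihood[nxt]) &
      !is.na(d$importance[nxt])
    i <- i[keep]; nxt <- nxt[keep]
    if (!length(i)) return(NULL)
    # feedback history: messages sent in gaps strictly before this pair's gap
    fb <- ifelse(is.na(d$feedback), 0L, d$feedback)
    cum_fb <- c(0L, cumsum(fb))   # shifted: cum_fb[t] = messages before gap t
    past <- cum_fb[i]
    s <- data.frame(person_id = d$person_id[i], session = d$session[i],
                    session_next = d$session[nxt], stringsAsFactors = FALSE)
    for (f in features) {
      s[[f]] <- d[[f]][i]
      s[[paste0(f, "_next")]] <- d[[f]][nxt]
    }
    s$action <- as.integer(d$feedback[i])
    s$effort <- d$effort[nxt]
    s$return_likelihood <- d$return_likelihood[nxt]
    s$n_past_feedback <- past
    s$any_past_feedback <- as.integer(past > 0L)
    if ("priority_level" %in% names(d)) s$priority_level <- d$priority_level[i]
    s
  })
  out <- do.call(rbind, out)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  out
}

#' Impute missing state-feature values with the sample population median
#'
#' Fills remaining gaps in the state-feature columns (current and next
#' session) with the corresponding feature's median over all non-missing
#' sample values of that feature (current and next pooled). Effort, return
#' likelihood, and next-session importance are non-missing by construction
#' of [build_interaction_samples()].
#'
#' @param samples interaction-sample table.
#' @return the table with gaps filled; attribute `imputations` holds the
#'   per-feature imputation counts.
#' @export
impute_missing_features <- function(samples) {
  features <- c("importance", "self_efficacy", "appreciation", "energy",
                "activity_difficulty")
  counts <- integer(0)
  for (f in features) {
    cols <- c(f, paste0(f, "_next"))
    cols <- cols[cols %in% names(samples)]
    pooled <- unlist(samples[cols], use.names = FALSE)
    n_miss <- sum(is.na(pooled))
    if (n_miss == 0L) { counts[f] <- 0L; next }
    if (all(is.na(pooled)))
      stop("feature '", f, "' is entirely missing; no median defined",
           call. = FALSE)
    med <- stats::median(pooled, na.rm = TRUE)
    for (cc in cols) samples[[cc]][is.na(samples[[cc]])] <- med
    counts[f] <- n_miss
  }
  attr(samples, "imputations") <- counts
  samples
}

#' Abstract a numeric feature into percentile levels
#'
#' Two levels: values less than or equal to the median become 0, values
#' greater become 1. Three levels: tertile cuts at the 33.3rd and 66.7th
#' percentiles with the same ties-to-lower rule. Cut points are returned so
#' the identical abstraction can be re-applied to new values (e.g., the
#' next-session features, or simulated people).
#'
#' @param values numeric vector (used to compute cut points when
#'   `cut_points` is `NULL`).
#' @param n_levels 2 or 3.
#' @param cut_points optional pre-computed increasing cut points of length
#'   `n_levels - 1` to re-apply.
#' @return list with integer `levels` (0-based) and `cut_points`.
#' @export
percentile_abstract <- function(values, n_levels, cut_points = NULL) {
  if (!length(values)) stop("values must be non-empty", call. = FALSE)
  if (!n_levels %in% c(2L, 3L)) stop("n_levels must be 2 or 3", call. = FALSE)
  if (is.null(cut_points)) {
    probs <- if (n_levels == 2L) 0.5 else c(1 / 3, 2 / 3)
    cut_points <- unname(stats::quantile(values, probs, na.rm = TRUE, type = 7))
  }
  levels <- rowSums(outer(values, cut_points, `>`))
  if (anyDuplicated(cut_points) ||
      isTRUE(stats::var(values, na.rm = TRUE) == 0))
    warning("degenerate abstraction: cut points do not separate the values",
            call. = FALSE)
  list(levels = as.integer(levels), cut_points = cut_points)
}

state_labels_from_levels <- function(level_matrix) {
  apply(level_matrix, 1L, paste, collapse = "")
}

all_state_labels <- function(schedule) {
  grids <- lapply(schedule, function(k) 0:(k - 1L))
  g <- expand.grid(rev(grids))[, rev(seq_along(schedule)), drop = FALSE]
  sort(apply(g, 1L, paste, collapse = ""))
}

feature_column <- function(samples, feature, when = c("now", "next")) {
  when <- match.arg(when)
  if (feature == "session") {
    if (when == "now") samples$session else samples$session_next
  } else {
    col <- if (when == "now") feature else paste0(feature, "_next")
    samples[[col]]
  }
}

#' Greedy state-feature selection by Q-value differences
#'
#' Iteratively selects the state features whose abstracted values lead to the
#' most different Q-values, in the spirit of the G-algorithm: at each step,
#' every remaining candidate is abstracted to the scheduled number of levels,
#' a finite MDP is estimated over (already-selected features x candidate),
#' solved by Gauss-Seidel value iteration, and the candidate is scored by the
#' maximum over actions and candidate-level pairs of the absolute Q
#' difference, averaged over the level combinations of the already-selected
#' features. Ties break by candidate declaration order.
#'
#' @param samples interaction samples (imputed).
#' @param candidate_features character vector of candidate names; `"session"`
#'   refers to the session number.
#' @param schedule level counts per selection step (default `c(3, 2, 2)`).
#' @param gamma discount factor for the scoring MDPs.
#' @param lambda transition pseudo-count used while scoring.
#' @return an `abstraction_spec`: list with `features`, `schedule`,
#'   `cut_points` (named list), `state_labels`, and per-step `scores`.
#' @export
select_base_features <- function(samples,
                                 candidate_features = c("importance",
                                                        "self_efficacy",
                                                        "appreciation",
                                                        "energy",
                                                        "activity_difficulty",
                                                        "session"),
                                 schedule = c(3L, 2L, 2L),
                                 gamma = 0.85, lambda = 1) {
  selected <- character(0)
  cut_points <- list()
  score_log <- list()
  for (step in seq_along(schedule)) {
    n_lev <- schedule[step]
    remaining <- setdiff(candidate_features, selected)
    if (!length(remaining))
      stop("not enough candidate features for the schedule", call. = FALSE)
    scores <- stats::setNames(numeric(length(remaining)), remaining)
    cand_cuts <- list()
    for (f in remaining) {
      ab <- percentile_abstract(feature_column(samples, f, "now"), n_lev)
      cand_cuts[[f]] <- ab$cut_points
      trial_feats <- c(selected, f)
      trial_sched <- c(schedule[seq_len(step - 1L)], n_lev)
      trial_cuts <- c(cut_points, stats::setNames(list(ab$cut_points), f))
      lv_now <- sapply(seq_along(trial_feats), function(k)
        percentile_abstract(feature_column(samples, trial_feats[k], "now"),
                            trial_sched[k], trial_cuts[[k]])$levels)
      lv_nxt <- sapply(seq_along(trial_feats), function(k)
        percentile_abstract(feature_column(samples, trial_feats[k], "next"),
                            trial_sched[k], trial_cuts[[k]])$levels)
      lv_now <- matrix(lv_now, ncol = length(trial_feats))
      lv_nxt <- matrix(lv_nxt, ncol = length(trial_feats))
      st <- state_labels_from_levels(lv_now)
      st_nxt <- state_labels_from_levels(lv_nxt)
      labels <- all_state_labels(trial_sched)
      if (length(setdiff(labels, unique(st))))
        message("feature '", f, "': some abstracted states unobserved; ",
                "scored with estimated fallback cells")
      mdp <- fit_mdp_from_states(st, st_nxt, samples$action, samples$effort,
                                 labels, gamma = gamma, lambda = lambda)
      sol <- gauss_seidel_value_iteration(mdp)
      # contexts: level combinations of already-selected features
      ctx <- if (length(selected)) {
        all_state_labels(schedule[seq_len(step - 1L)])
      } else ""
      vals <- 0:(n_lev - 1L)
      pair_scores <- c()
      for (a in 1:2) for (v1i in seq_along(vals)) for (v2i in seq_along(vals)) {
        if (v2i <= v1i) next
        d <- mean(abs(sol$Q[paste0(ctx, vals[v1i]), a] -
                      sol$Q[paste0(ctx, vals[v2i]), a]))
        pair_scores <- c(pair_scores, d)
      }
      scores[f] <- max(pair_scores)
    }
    best <- remaining[which.max(scores)]  # which.max keeps declaration order on ties
    selected <- c(selected, best)
    cut_points[[best]] <- cand_cuts[[best]]
    score_log[[step]] <- scores
  }
  spec <- list(features = selected, schedule = as.integer(schedule),
               cut_points = cut_points,
               state_labels = all_state_labels(schedule),
               scores = score_log)
  class(spec) <- "abstraction_spec"
  spec
}

#' Apply an abstraction spec to interaction samples
#'
#' Adds `state` and `state_next` labels (digit strings, one digit per
#' selected feature) using the spec's frozen cut points.
#'
#' @param samples interaction samples.
#' @param spec an `abstraction_spec` from [select_base_features()].
#' @return samples with `state` and `state_next` columns.
#' @export
abstract_states <- function(samples, spec) {
  stopifnot(inherits(spec, "abstraction_spec"))
  lv_now <- sapply(seq_along(spec$features), function(k)
    percentile_abstract(feature_column(samples, spec$features[k], "now"),
                        spec$schedule[k], spec$cut_points[[spec$features[k]]])$levels)
  lv_nxt <- sapply(seq_along(spec$features), function(k)
    percentile_abstract(feature_column(samples, spec$features[k], "next"),
                        spec$schedule[k], spec$cut_points[[spec$features[k]]])$levels)
  samples$state <- state_labels_from_levels(matrix(lv_now, nrow = nrow(samples)))
  samples$state_next <- state_labels_from_levels(matrix(lv_nxt, nrow = nrow(samples)))
  samples
}

#' Serialize an abstraction spec to JSON
#' @param spec an `abstraction_spec`.
#' @param path file path.
#' @export
write_abstraction_spec <- function(spec, path) {
  jsonlite::write_json(
    list(features = spec$features, schedule = spec$schedule,
         cut_points = spec$cut_points, state_labels = spec$state_labels),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read an abstraction spec from JSON
#' @param path file path.
#' @export
read_abstraction_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  spec <- list(features = x$features, schedule = as.integer(x$schedule),
               cut_points = x$cut_points, state_labels = x$state_labels,
               scores = NULL)
  class(spec) <- "abstraction_spec"
  spec
}
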