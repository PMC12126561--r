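jags_ri_model <- "
model {
  for (i in 1:N) {
    y[i] ~ dnorm(mu + u[pid[i]] + inprod(beta[], X[i, ]), tau)
  }
  for (j in 1:J) {
    u[j] ~ dnorm(0, tau_u)
  }
  mu ~ dnorm(0, 0.01)
  for (k in 1:K) {
    beta[k] ~ dnorm(0, 0.01)
  }
  sigma ~ dnorm(0, 0.04) T(0,)
  sigma_u ~ dnorm(0, 0.04) T(0,)
  tau <- pow(sigma, -2)
  tau_u <- pow(sigma_u, -2)
}
"

#' Posterior summary of a fixed effect
#'
#' Summarizes coefficient draws as the analysis reports them: posterior
#' mean, 95% highest-density interval (narrowest interval containing 95% of
#' the draws), the posterior probability that the effect is positive, and a
#' standardized effect size computed as the posterior-mean coefficient over
#' the posterior-mean residual SD.
#'
#' @param b_draws numeric vector of coefficient draws (>= 1000).
#' @param sigma_draws numeric vector of residual-SD draws.
#' @param prob HDI mass (default 0.95).
#' @return list with `b`, `hdi` (length 2), `p_positive`, `cohens_d`.
#' @export
summarize_posterior <- function(b_draws, sigma_draws, prob = 0.95) {
  n <- length(b_draws)
  if (n < 1000L) stop("need at least 1000 posterior draws", call. = FALSE)
  s <- sort(b_draws)
  k <- max(1L, floor(prob * n))
  widths <- s[seq.int(k, n)] - s[seq_len(n - k + 1L)]
  i <- which.min(widths)
  list(b = mean(b_draws), hdi = c(s[i], s[i + k - 1L]),
       p_positive = mean(b_draws > 0),
       cohens_d = mean(b_draws) / mean(sigma_draws))
}

fit_ri_model <- function(samples, outcome, X, effect_index, effect_name,
                         seed, n_adapt = 500L, n_burn = 500L,
                         n_iter = 1500L, n_chains = 2L) {
  y <- samples[[outcome]]
  if (anyNA(y)) stop("outcome contains missing values", call. = FALSE)
  if (stats::var(y) == 0)
    stop("outcome has zero variance; model not identifiable", call. = FALSE)
  X <- as.matrix(X)
  for (k in seq_len(ncol(X)))
    if (stats::var(X[, k]) == 0)
      stop("covariate ", k, " is constant; effect not identifiable",
           call. = FALSE)
  if (ncol(X) >= 2L) {
    cc <- suppressWarnings(stats::cor(X))
    if (any(abs(cc[upper.tri(cc)]) > 0.999))
      warning("covariates are (nearly) collinear; the dose effect is ",
              "weakly identified", call. = FALSE)
  }
  pid <- as.integer(factor(samples$person_id))
  if (max(pid) < 2L) stop("need at least 2 persons", call. = FALSE)
  # centering the covariates decorrelates the grand mean from the slopes in
  # the sampler; the slopes themselves are unaffected
  Xc <- scale(X, center = TRUE, scale = FALSE)
  data <- list(y = as.numeric(y), X = Xc, pid = pid, N = length(y),
               J = max(pid), K = ncol(X))
  seed <- as.integer(seed)
  inits <- lapply(seq_len(n_chains), function(ch)
    list(.RNG.name = "base::Wichmann-Hill", .RNG.seed = seed + ch))
  jm <- rjags::jags.model(textConnection(jags_ri_model), data = data,
                          inits = inits, n.chains = n_chains,
                          n.adapt = n_adapt, quiet = TRUE)
  update(jm, n_burn, progress.bar = "none")
  post <- rjags::coda.samples(jm, c("beta", "sigma", "mu"), n.iter = n_iter,
                              progress.bar = "none")
  cn <- colnames(post[[1]])
  beta_name <- paste0("beta[", effect_index, "]")
  if (!beta_name %in% cn) beta_name <- "beta"
  b_draws <- unlist(lapply(post, function(ch) as.numeric(ch[, beta_name])))
  sigma_draws <- unlist(lapply(post, function(ch) as.numeric(ch[, "sigma"])))
  rhat <- tryCatch(
    coda::gelman.diag(post[, c(beta_name, "sigma"), drop = FALSE],
                      autoburnin = FALSE, multivariate = FALSE)$psrf[, 1L],
    error = function(e) NA_real_)
  converged <- all(is.finite(rhat)) && all(rhat < 1.01)
  if (!converged)
    warning("split-Rhat >= 1.01 for '", effect_name,
            "'; treat the estimate with caution", call. = FALSE)
  est <- summarize_posterior(b_draws, sigma_draws)
  structure(c(est, list(outcome = outcome, effect = effect_name,
                        n_samples = length(y), n_persons = max(pid),
                        rhat = rhat, converged = converged)),
            class = "effect_estimate")
}

#' @export
print.effect_estimate <- function(x, ...) {
  cat(sprintf("%s effect on %s: b = %.3f, 95%% HDI = [%.3f, %.3f], P(b>0) = %.3f, d = %.3f\n",
              x$effect, x$outcome, x$b, x$hdi[1], x$hdi[2], x$p_positive,
              x$cohens_d))
  invisible(x)
}

#' Direct effect of human feedback on engagement
#'
#' Hierarchical normal model with a general mean, a random intercept per
#' person, and a binary fixed effect for feedback received after the
#' previous session, fit by MCMC with diffuse priors (normal(0, 10) on the
#' mean and coefficient, half-normal(0, 5) on the SDs).
#'
#' @param samples interaction samples (needs `person_id`, `action`, and the
#'   outcome column).
#' @param outcome `"effort"` or `"return_likelihood"`.
#' @param seed integer seed for the sampler.
#' @param ... sampler settings passed on (`n_adapt`, `n_burn`, `n_iter`,
#'   `n_chains`).
#' @return an `effect_estimate`.
#' @export
fit_direct_effect <- function(samples, outcome = c("effort",
                                                   "return_likelihood"),
                              seed = 1L, ...) {
  outcome <- match.arg(outcome)
  fit_ri_model(samples, outcome, cbind(direct = samples$action), 1L,
               "direct", seed, ...)
}

#' Delayed effect of human feedback on engagement
#'
#' As [fit_direct_effect()] but with the any-past-feedback indicator
#' (feedback received in any gap before the most recent one).
#'
#' @inheritParams fit_direct_effect
#' @return an `effect_estimate`.
#' @export
fit_delayed_effect <- function(samples, outcome = c("effort",
                                                    "return_likelihood"),
                               seed = 1L, ...) {
  outcome <- match.arg(outcome)
  fit_ri_model(samples, outcome, cbind(delayed = samples$any_past_feedback),
               1L, "delayed", seed, ...)
}

#' Dose effect of multiple human feedback messages
#'
#' Extends the delayed model with a fixed effect for the number of feedback
#' messages received so far; the reported estimate is the count coefficient.
#'
#' @inheritParams fit_direct_effect
#' @return an `effect_estimate`.
#' @export
fit_dose_effect <- function(samples, outcome = c("effort",
                                                 "return_likelihood"),
                            seed = 1L, ...) {
  outcome <- match.arg(outcome)
  if (length(unique(samples$n_past_feedback)) < 2L)
    stop("feedback count is constant; dose effect not identifiable",
         call. = FALSE)
  fit_ri_model(samples, outcome,
               cbind(delayed = samples$any_past_feedback,
                     dose = samples$n_past_feedback),
               2L, "dose", seed, ...)
}
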