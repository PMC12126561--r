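#' Default end-to-end run configuration
#'
#' Collects every stage's settings in one serializable list. Each stochastic
#' stage derives its own seed from the global seed by a fixed small offset,
#' so a single integer reproduces the whole run.
#'
#' @param seed global integer seed.
#' @param n_persons cohort size.
#' @return a nested `run_config` list.
#' @export
default_run_config <- function(seed = 42L, n_persons = 679L) {
  seed <- as.integer(seed)
  cfg <- list(
    seed = seed,
    generator = list(n_persons = as.integer(n_persons), seed = seed),
    abstraction = list(schedule = c(3L, 2L, 2L)),
    mdp = list(gamma = 0.85, lambda = 1),
    planning = list(epsilon = 0.001),
    simulation = list(horizon = 100L,
                      costs = c(0, 0.02, 0.03, 0.05, 0.055, 0.07, 0.09, 0.1,
                                0.102, 0.12, 0.18)),
    live_app = list(n_spots = 166L, n_sessions = 9L, dropout = 0.15,
                    capacity = 0.35, n_days = 200L, seed = seed + 2L),
    inference = list(enabled = TRUE, seed = seed + 3L,
                     n_adapt = 500L, n_burn = 500L, n_iter = 1500L,
                     n_chains = 2L)
  )
  class(cfg) <- c("run_config", "list")
  cfg
}

#' Write / read a run configuration as YAML
#' @param config a `run_config`.
#' @param path file path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  class(cfg) <- c("run_config", "list")
  cfg
}

stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full analysis pipeline
#'
#' Executes generate -> preprocess -> estimate -> plan -> simulate ->
#' ethical allocation -> (optionally) effect inference, writing every
#' artifact (CSV tables, JSON models, YAML config) plus a manifest into
#' `out_dir`.
#'
#' @param config a [default_run_config()]-style list.
#' @param out_dir output directory, created if missing.
#' @return invisibly, a list with the in-memory results of each stage.
#' @export
run_pipeline <- function(config = default_run_config(), out_dir) {
  if (!dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
    message("created output directory ", out_dir)
  }
  write_run_config(config, file.path(out_dir, "config.yaml"))

  cohort <- stage("generate", {
    gc <- cohort_config(n_persons = config$generator$n_persons,
                        seed = config$generator$seed)
    generate_cohort(gc)
  })
  utils::write.csv(cohort, file.path(out_dir, "cohort.csv"),
                   row.names = FALSE)

  pre <- stage("preprocess", {
    samples <- impute_missing_features(build_interaction_samples(cohort))
    spec <- select_base_features(samples,
                                 schedule = config$abstraction$schedule,
                                 gamma = config$mdp$gamma,
                                 lambda = config$mdp$lambda)
    list(samples = abstract_states(samples, spec), spec = spec)
  })
  utils::write.csv(pre$samples, file.path(out_dir, "samples.csv"),
                   row.names = FALSE)
  write_abstraction_spec(pre$spec, file.path(out_dir, "abstraction.json"))

  mdp <- stage("estimate", fit_mdp(pre$samples, pre$spec,
                                   gamma = config$mdp$gamma,
                                   lambda = config$mdp$lambda))
  write_mdp(mdp, file.path(out_dir, "mdp.json"))

  plan <- stage("plan", gauss_seidel_value_iteration(
    mdp, epsilon = config$planning$epsilon))
  jsonlite::write_json(list(policy = as.list(plan$policy), Q = plan$Q,
                            V = as.list(plan$V)),
                       file.path(out_dir, "policy.json"),
                       auto_unbox = TRUE, digits = NA)

  sim <- stage("simulate", {
    init <- initial_state_distribution(pre$samples, mdp$states)
    four <- simulate_policies(mdp, init, config$simulation$horizon)
    sweep <- cost_sweep(mdp, config$simulation$costs, init,
                        config$simulation$horizon)
    list(init = init, four = four, sweep = sweep)
  })
  utils::write.csv(sim$four, file.path(out_dir, "policy_trajectories.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(sim$sweep$policies),
                   file.path(out_dir, "cost_sweep_policies.csv"))
  utils::write.csv(sim$sweep$trajectories,
                   file.path(out_dir, "cost_sweep_trajectories.csv"),
                   row.names = FALSE)
  jsonlite::write_json(as.list(sim$init),
                       file.path(out_dir, "initial_distribution.json"),
                       auto_unbox = TRUE, digits = NA)

  eth <- stage("ethical", {
    app_digit <- match("appreciation", pre$spec$features)
    if (is.na(app_digit))
      stop("appreciation not among the selected base features; ",
           "the autonomy reward is undefined")
    lac <- live_app_config(n_spots = config$live_app$n_spots,
                           n_sessions = config$live_app$n_sessions,
                           dropout = config$live_app$dropout,
                           capacity = config$live_app$capacity,
                           seed = config$live_app$seed)
    cmp <- compare_principle_policies(mdp, sim$init, lac,
                                      appreciation_digit = app_digit)
    list(config = lac, comparison = cmp, appreciation_digit = app_digit)
  })
  utils::write.csv(eth$comparison$shares,
                   file.path(out_dir, "subgroup_shares.csv"),
                   row.names = FALSE)
  yaml::write_yaml(list(costs = as.list(eth$comparison$costs),
                        fractions = as.list(eth$comparison$fractions)),
                   file.path(out_dir, "tuned_costs.yaml"))

  inf <- NULL
  if (isTRUE(config$inference$enabled)) {
    inf <- stage("infer", {
      s <- config$inference
      ests <- list(
        direct_effort = fit_direct_effect(pre$samples, "effort", s$seed,
                                          n_adapt = s$n_adapt,
                                          n_burn = s$n_burn,
                                          n_iter = s$n_iter,
                                          n_chains = s$n_chains),
        delayed_effort = fit_delayed_effect(pre$samples, "effort", s$seed,
                                            n_adapt = s$n_adapt,
                                            n_burn = s$n_burn,
                                            n_iter = s$n_iter,
                                            n_chains = s$n_chains),
        delayed_return = fit_delayed_effect(pre$samples, "return_likelihood",
                                            s$seed, n_adapt = s$n_adapt,
                                            n_burn = s$n_burn,
                                            n_iter = s$n_iter,
                                            n_chains = s$n_chains),
        dose_effort = fit_dose_effect(pre$samples, "effort", s$seed,
                                      n_adapt = s$n_adapt, n_burn = s$n_burn,
                                      n_iter = s$n_iter,
                                      n_chains = s$n_chains)
      )
      ests
    })
    tab <- do.call(rbind, lapply(names(inf), function(nm) {
      e <- inf[[nm]]
      data.frame(model = nm, outcome = e$outcome, effect = e$effect,
                 b = e$b, hdi_lo = e$hdi[1], hdi_hi = e$hdi[2],
                 p_positive = e$p_positive, cohens_d = e$cohens_d,
                 n_samples = e$n_samples, stringsAsFactors = FALSE)
    }))
    utils::write.csv(tab, file.path(out_dir, "effect_estimates.csv"),
                     row.names = FALSE)
  }

  manifest <- list(
    seed = config$seed,
    r_version = as.character(getRversion()),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
    config_md5 = unname(tools::md5sum(file.path(out_dir, "config.yaml"))),
    artifacts = list.files(out_dir)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE)
  invisible(list(cohort = cohort, samples = pre$samples, spec = pre$spec,
                 mdp = mdp, plan = plan, simulation = sim, ethics = eth,
                 inference = inf))
}
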