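# Artifact formats

All artifacts are plain text: CSV with a header row (UTF-8), JSON, or YAML.

## cohort.csv
One row per attended person-session.
`person_id, session, priority_level, latent_intercept, importance,
self_efficacy, appreciation, energy, activity_difficulty, feedback,
effort, return_likelihood`.
`feedback` is the 0/1 assignment for the gap *after* the session (empty for
the last attended session); `effort` and `return_likelihood` are empty in
session 1.

## cohort_config.yaml
The generator settings (scalar fields of `cohort_config()`).

## principle_points.csv
One row per questionnaire respondent; 11 integer columns summing to 100.

## samples.csv
One row per interaction sample (pair of consecutive attended sessions):
`person_id, session, session_next`, the five state features at the first
session and `*_next` at the second, `action`, `effort`,
`return_likelihood`, `n_past_feedback`, `any_past_feedback`,
`priority_level`, and after abstraction `state`, `state_next` (digit
strings).

## abstraction.json
`features` (ordered selected features), `schedule` (levels per feature),
`cut_points` (per feature), `state_labels`.

## mdp.json
`states`, `R` (|S| x 2), `T0`/`T1` (|S| x |S| row-stochastic matrices for
action 0/1), `gamma`, `mean_effort`.

## base_policy.json / policy.json
Per-state action (0/1) and value; `policy.json` additionally carries Q.

## initial_distribution.json
Probability per base-state label (first-session empirical).

## policy_trajectories.csv / cost_sweep_trajectories.csv
Tidy: `policy, t, mean_reward, feedback_fraction` (+ `cost` in the sweep).

## cost_sweep_policies.csv
Rows = policies π*,c over the cost grid, columns = the 12 state labels,
cells 0/1.

## ethical_tuning.yaml
Five-principle weights, tuned cost, and achieved steady-state feedback
fraction per policy.

## subgroup_shares.csv / subgroup_report_agent.csv
Tidy: `criterion, level, share` (+ `policy` for the six-policy
comparison); shares are percentages summing to 100 per criterion.

## allocation_log.csv
Agent-based live-application log:
`day, person_id, state, priority, time_since_feedback, action`.

## effect_estimates.csv
`model, outcome, effect, b, hdi_lo, hdi_hi, p_positive, cohens_d,
n_samples`.

## manifest.json
Global seed, R version, timestamp, config hash, artifact list.
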