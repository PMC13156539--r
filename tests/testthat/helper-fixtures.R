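# Small-scale configurations for fast tests; study-scale defaults are
# exercised in the acceptance suite.
small_config <- function(n = 20, seed = 1, ...) {
  trial_config(n_per_arm = n, m = 3, n_bootstrap = 200, seed = seed, ...)
}

# single-instrument parameter set (keeps simulation loops cheap)
sis_only_params <- function(effect_t1 = -5.83, effect_t2 = -7.79) {
  op <- default_outcome_params()["sis", , drop = FALSE]
  op$effect_t1 <- effect_t1
  op$effect_t2 <- effect_t2
  op
}

# participant-level CEA dataset with known incremental cost/QALY
synthetic_cohort <- function(n_per_arm = 96, delta_cost = 0,
                             delta_qaly = 0.01, seed = 1) {
  set.seed(seed)
  g <- rep(c(1, 0), each = n_per_arm)
  base_u <- rnorm(2 * n_per_arm, 0.66, 0.1)
  data.frame(
    participant_id = sprintf("S%03d", seq_len(2 * n_per_arm)),
    arm = ifelse(g == 1, "intervention", "control"),
    endocrine_therapy = rbinom(2 * n_per_arm, 1, 0.6),
    baseline_utility = base_u,
    cost = 9000 + delta_cost * g + rnorm(2 * n_per_arm, 0, 500),
    qaly = 0.34 + delta_qaly * g + 0.15 * (base_u - 0.66) +
      rnorm(2 * n_per_arm, 0, 0.03),
    stringsAsFactors = FALSE)
}
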