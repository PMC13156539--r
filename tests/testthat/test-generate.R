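test_that("a generated panel has one row per participant per timepoint", {
  panel <- generate_trial(trial_config(seed = 1))
  expect_equal(nrow(panel), 192 * 3)
  counts <- table(panel$participant_id)
  expect_true(all(counts == 3))
  expect_equal(sum(panel$arm == "intervention"), 96 * 3)
})

test_that("generation is deterministic given config and seed", {
  cfg <- small_config(seed = 42)
  expect_identical(generate_trial(cfg), generate_trial(cfg))
  cfg2 <- small_config(seed = 43)
  expect_false(identical(generate_trial(cfg), generate_trial(cfg2)))
})

test_that("scores respect instrument ranges and integer scale totals", {
  panel <- generate_trial(small_config(n = 60, seed = 3))
  op <- default_outcome_params()
  for (v in op$instrument) {
    expect_true(all(panel[[v]] >= op[v, "range_min"] &
                      panel[[v]] <= op[v, "range_max"]), label = v)
    if (op[v, "integer"])
      expect_true(all(panel[[v]] == round(panel[[v]])), label = v)
  }
  expect_true(all(panel$direct_cost >= 0))
  usage <- panel[panel$arm == "intervention", "usage_minutes_total"]
  expect_true(all(usage >= 0))
})

test_that("with zero effects the arm difference is centred at zero", {
  op <- sis_only_params(effect_t1 = 0, effect_t2 = 0)
  diffs <- matrix(NA_real_, 200, 2)
  for (r in seq_len(200)) {
    panel <- generate_trial(trial_config(outcome_params = op,
                                         within_subject_rho = 0,
                                         seed = 1000 + r))
    for (j in 1:2) {
      d <- panel[panel$timepoint == c("T1", "T2")[j], ]
      diffs[r, j] <- mean(d$sis[d$arm == "intervention"]) -
        mean(d$sis[d$arm == "control"])
    }
  }
  for (j in 1:2) {
    mc_se <- sd(diffs[, j]) / sqrt(nrow(diffs))
    expect_lt(abs(mean(diffs[, j])), 3 * mc_se)
  }
})

test_that("a configured stigma effect is recovered at large n", {
  panel <- generate_trial(trial_config(n_per_arm = 2000,
                                       outcome_params = sis_only_params(),
                                       seed = 7))
  d <- panel[panel$timepoint == "T1", ]
  diff_t1 <- mean(d$sis[d$arm == "intervention"]) -
    mean(d$sis[d$arm == "control"])
  mc_se <- 9.50 * sqrt(2 / 2000)
  expect_lt(abs(diff_t1 - (-5.83)), 3 * mc_se)
})

test_that("marginal moments and within-subject correlation are recovered", {
  op <- default_outcome_params()["mcs", , drop = FALSE]  # mid-range scale
  panel <- generate_trial(trial_config(n_per_arm = 5000,
                                       outcome_params = op,
                                       within_subject_rho = 0.5, seed = 9))
  ctrl <- panel[panel$arm == "control", ]
  base <- ctrl$mcs[ctrl$timepoint == "T0"]
  expect_lt(abs(mean(base) - 40.76), 3 * 10.37 / sqrt(5000))
  expect_lt(abs(sd(base) - 10.37), 0.4)
  t1 <- ctrl$mcs[ctrl$timepoint == "T1"]
  expect_lt(abs(mean(t1) - (40.76 + 1.03)), 3 * 10.37 / sqrt(5000))
  expect_lt(abs(cor(base, t1) - 0.5), 0.03)
})

test_that("dropout never touches baseline and is monotone", {
  cfg <- small_config(n = 96, seed = 5)
  panel <- apply_missingness(generate_trial(cfg), 0.3, "MAR", seed = 6)
  base <- panel[panel$timepoint == "T0", panel_instruments(panel)]
  expect_false(anyNA(base))
  t1_na <- is.na(panel$sis[panel$timepoint == "T1"])
  t2_na <- is.na(panel$sis[panel$timepoint == "T2"])
  expect_true(all(t2_na[t1_na]))  # missing T1 implies missing T2
  expect_identical(apply_missingness(generate_trial(cfg), 0, "MCAR"),
                   generate_trial(cfg))
  expect_error(apply_missingness(generate_trial(cfg), 1.0, "MCAR"), "rate")
})

test_that("MCAR dropout hits the target rate on average", {
  cfg <- trial_config(outcome_params = sis_only_params(), seed = 0)
  frac <- vapply(seq_len(60), function(r) {
    panel <- apply_missingness(generate_trial(cfg), 37 / 192, "MCAR",
                               seed = 500 + r)
    t12 <- panel[panel$timepoint != "T0", ]
    mean(tapply(is.na(t12$sis), t12$participant_id, any))
  }, numeric(1))
  mc_se <- sd(frac) / sqrt(length(frac))
  expect_lt(abs(mean(frac) - 37 / 192), 3 * mc_se)
})

test_that("MAR dropout selects on the observed baseline score", {
  cfg <- trial_config(outcome_params = sis_only_params(), seed = 0)
  gap <- vapply(seq_len(40), function(r) {
    panel <- apply_missingness(generate_trial(cfg), 0.25, "MAR",
                               seed = 700 + r, beta_baseline = 0.8)
    t1 <- panel[panel$timepoint == "T1", ]
    dropped <- is.na(t1$sis) |
      t1$participant_id %in% panel$participant_id[
        panel$timepoint == "T2" & is.na(panel$sis)]
    base <- panel[panel$timepoint == "T0", ]
    mean(base$sis[dropped]) - mean(base$sis[!dropped])
  }, numeric(1))
  expect_gt(mean(gap), 0)  # dropouts have higher baseline stigma
})

test_that("panels survive a CSV round trip and bad files are rejected", {
  panel <- apply_missingness(generate_trial(small_config(n = 10, seed = 2)),
                             0.2, "MCAR", seed = 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_panel(panel, path)
  back <- read_panel(path)
  expect_equal(as.data.frame(back)$sis, as.data.frame(panel)$sis)
  expect_equal(dim(back), dim(panel))

  bad <- as.data.frame(panel)
  bad$arm <- NULL
  path2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(bad, path2, row.names = FALSE)
  expect_error(read_panel(path2), "arm")
})
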