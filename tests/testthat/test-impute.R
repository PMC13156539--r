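test_that("Rubin's rules pooling matches hand arithmetic", {
  p <- pool_rubin(c(1, 1, 1), c(4, 4, 4))
  expect_equal(p$point, 1)
  expect_equal(p$within_var, 4)
  expect_equal(p$between_var, 0)
  expect_equal(p$total_var, 4)

  p <- pool_rubin(c(0, 2), c(1, 1))
  expect_equal(p$point, 1)
  expect_equal(p$within_var, 1)
  expect_equal(p$between_var, 2)
  expect_equal(p$total_var, 1 + (1 + 1 / 2) * 2)  # 4
  expect_equal(p$df, (2 - 1) * (1 + 1 / 3)^2)

  p1 <- pool_rubin(3.2, 0.7)
  expect_equal(p1$total_var, 0.7)
  expect_equal(p1$between_var, 0)

  # total variance is monotone in the spread of the points
  t_narrow <- pool_rubin(c(1, 1.1, 0.9), c(1, 1, 1))$total_var
  t_wide <- pool_rubin(c(0, 2, 1), c(1, 1, 1))$total_var
  expect_gt(t_wide, t_narrow)
  expect_error(pool_rubin(numeric(0), numeric(0)), "no estimates")
  expect_error(pool_rubin(c(1, 2), c(1, -1)), "positive variance")
})

test_that("a complete panel passes through imputation unchanged", {
  panel <- generate_trial(small_config(n = 12, seed = 4))
  imps <- impute_panel(panel, m = 3, seed = 5)
  for (p in imps$panels) expect_identical(p, panel)
})

test_that("imputation fills only the missing cells, within range", {
  panel <- apply_missingness(generate_trial(small_config(n = 40, seed = 6)),
                             0.3, "MAR", seed = 7)
  for (method in c("chained", "mcmc")) {
    imps <- impute_panel(panel, m = 2, method = method, seed = 8)
    op <- default_outcome_params()
    for (p in imps$panels) {
      expect_false(anyNA(as.data.frame(p)[panel_instruments(p)]))
      for (v in panel_instruments(p)) {
        obs <- !is.na(panel[[v]])
        expect_equal(p[[v]][obs], panel[[v]][obs])  # observed cells intact
        expect_true(all(p[[v]] >= op[v, "range_min"] &
                          p[[v]] <= op[v, "range_max"]))
      }
    }
  }
  expect_error(impute_panel(panel, m = 0), "m")
})

test_that("missing baseline values are a design violation", {
  panel <- generate_trial(small_config(n = 10, seed = 9))
  panel$sis[panel$timepoint == "T0"][1] <- NA
  expect_error(impute_panel(panel, m = 1), "baseline")
})

test_that("pooled arm differences are unbiased under MCAR", {
  op <- sis_only_params()
  err <- vapply(seq_len(200), function(r) {
    cfg <- trial_config(n_per_arm = 60, outcome_params = op,
                        seed = 2000 + r)
    full <- generate_trial(cfg)
    t1 <- full[full$timepoint == "T1", ]
    truth <- mean(t1$sis[t1$arm == "intervention"]) -
      mean(t1$sis[t1$arm == "control"])
    panel <- apply_missingness(full, 0.2, "MCAR", seed = 3000 + r)
    imps <- impute_panel(panel, m = 5, seed = 4000 + r)
    est <- mean(vapply(imps$panels, function(p) {
      d <- p[p$timepoint == "T1", ]
      mean(d$sis[d$arm == "intervention"]) - mean(d$sis[d$arm == "control"])
    }, numeric(1)))
    est - truth
  }, numeric(1))
  mc_se <- sd(err) / sqrt(length(err))
  expect_lt(abs(mean(err)), 3 * mc_se)
})

test_that("chained and joint-normal imputation agree on the stigma contrast", {
  cfg <- trial_config(outcome_params = sis_only_params(), seed = 31)
  panel <- apply_missingness(generate_trial(cfg), 37 / 192, "MAR", seed = 32)
  ct <- lapply(c("chained", "mcmc"), function(meth) {
    imps <- impute_panel(panel, m = 10, method = meth, seed = 33)
    group_contrast(fit_gee(imps, "sis"), "T1")
  })
  gap <- abs(ct[[1]]$estimate - ct[[2]]$estimate)
  expect_lt(gap, 0.5 * max(ct[[1]]$se, ct[[2]]$se))
})

test_that("with no missing data pooled contrasts equal the single fit", {
  panel <- generate_trial(small_config(n = 30, seed = 35))
  imps <- impute_panel(panel, m = 4, seed = 36)
  ct_pooled <- group_contrast(fit_gee(imps, "sis"), "T2")
  ct_single <- group_contrast(fit_gee(panel, "sis"), "T2")
  expect_equal(ct_pooled$estimate, ct_single$estimate)
  expect_equal(ct_pooled$se, ct_single$se)
  expect_equal(ct_pooled$p_bonferroni, ct_single$p_bonferroni)
})
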