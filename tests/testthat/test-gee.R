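test_that("estimating equations reduce to least squares under independence", {
  set.seed(1)
  n <- 40
  X <- cbind(1, rbinom(n, 1, 0.5), rnorm(n))
  y <- X %*% c(2, -1, 0.5) + rnorm(n)
  f <- gee_exchangeable(as.vector(y), X, id = seq_len(n),
                        corstr = "independence")
  ols <- qr.coef(qr(X), y)
  expect_lt(max(abs(f$beta - ols)), 1e-8)
  expect_true(f$converged)
  expect_equal(f$alpha, 0)
})

test_that("sandwich equals model-based covariance for homogeneous residuals", {
  # intercept-only fit with residuals of constant magnitude: the empirical
  # meat equals sigma^2 X'X up to the (n-p)/n variance-denominator factor
  y <- rep(c(1, 3), 10)
  X <- matrix(1, 20, 1)
  f <- gee_exchangeable(y, X, id = seq_len(20), corstr = "independence")
  expect_equal(f$vcov_robust[1, 1],
               f$vcov_naive[1, 1] * (20 - 1) / 20, tolerance = 1e-12)
})

test_that("duplicating every cluster leaves the point estimates unchanged", {
  panel <- generate_trial(small_config(n = 5, seed = 21))
  dup <- as.data.frame(panel)
  dup$participant_id <- paste0(dup$participant_id, "_copy")
  both <- rbind(as.data.frame(panel), dup)
  class(both) <- class(panel)
  f1 <- fit_gee(panel, "sis")
  f2 <- fit_gee(both, "sis")
  expect_equal(f1$fits[[1]]$beta, f2$fits[[1]]$beta, tolerance = 1e-6)
})

test_that("configured effects are recovered within robust error at large n", {
  panel <- generate_trial(trial_config(n_per_arm = 2000,
                                       outcome_params = sis_only_params(),
                                       seed = 23))
  fit <- fit_gee(panel, "sis")
  expect_true(fit$converged)
  f <- fit$fits[[1]]
  expect_true(f$alpha > -1 && f$alpha < 1)
  ct1 <- group_contrast(fit, "T1")
  ct2 <- group_contrast(fit, "T2")
  expect_lt(abs(ct1$estimate - (-5.83)), 3 * ct1$se)
  expect_lt(abs(ct2$estimate - (-7.79)), 3 * ct2$se)
  expect_error(group_contrast(fit, "T9"), "timepoint")
})

test_that("Bonferroni adjustment caps at one and is monotone in k", {
  fit <- fit_gee(generate_trial(small_config(n = 25, seed = 24)), "psqi")
  c1 <- group_contrast(fit, "T1", k_comparisons = 1)
  c2 <- group_contrast(fit, "T1", k_comparisons = 2)
  c6 <- group_contrast(fit, "T1", k_comparisons = 6)
  expect_equal(c1$p_bonferroni, c1$p_raw)
  expect_true(c1$p_bonferroni <= c2$p_bonferroni)
  expect_true(c2$p_bonferroni <= c6$p_bonferroni)
  expect_equal(min(1, 2 * 0.6), 1)  # cap rule on a large raw p
  expect_true(all(c(c1$p_bonferroni, c2$p_bonferroni, c6$p_bonferroni) <= 1))
  expect_true(c1$ci[1] <= c1$estimate && c1$estimate <= c1$ci[2])
})

test_that("pooled baseline SD, Cohen's d and MICD match hand evaluation", {
  expect_equal(pooled_baseline_sd(9.09, 9.93, 96, 96),
               sqrt((95 * 9.09^2 + 95 * 9.93^2) / 190))
  expect_equal(round(pooled_baseline_sd(9.09, 9.93, 96, 96), 2), 9.52)
  expect_equal(round(pooled_baseline_sd(5.83, 6.37, 96, 96), 2), 6.11)
  expect_equal(pooled_baseline_sd(3, 3, 50, 50), 3)  # equal-variance identity
  expect_error(pooled_baseline_sd(-1, 2, 10, 10), "SD")

  expect_equal(round(cohens_d(-7.79, 9.50), 2), -0.82)
  expect_equal(round(cohens_d(-1.91, 6.09), 2), -0.31)
  expect_equal(cohens_d(0, 5), 0)
  expect_error(cohens_d(1, 0), "pooled_sd")

  expect_equal(micd(9.50), 4.75)
  expect_equal(micd(2), 1)
  expect_true(abs(-7.79) > micd(9.50))   # stigma contrast is clinically
  expect_false(abs(-1.91) > micd(6.09))  # meaningful; body image is not
  expect_error(micd(0), "baseline_sd")
})

test_that("the effects table carries consistent columns and flags", {
  panel <- generate_trial(small_config(n = 40, seed = 26))
  tab <- effects_table(panel, outcomes = c("sis", "bis"))
  expect_equal(nrow(tab), 4)
  expect_true(all(tab$ci_low <= tab$difference &
                    tab$difference <= tab$ci_high))
  expect_true(all(tab$p_bonferroni >= tab$p_raw & tab$p_bonferroni <= 1))
  # d column is difference over pooled unadjusted baseline SD
  base <- baseline_table(panel)
  for (i in seq_len(nrow(tab))) {
    b <- base[base$variable == tab$outcome[i], ]
    sd_pool <- pooled_baseline_sd(b$sd_intervention, b$sd_control, 40, 40)
    expect_equal(tab$cohen_d[i], tab$difference[i] / sd_pool)
  }
})
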