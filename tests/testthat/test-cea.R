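test_that("ICER labelling covers the plane and reproduces the ratio", {
  r <- icer(155.45, 0.008)
  expect_equal(r$label, "ratio")
  expect_equal(r$value, 19431.25)
  expect_equal(icer(-10, 0.01)$label, "intervention-dominant")
  expect_equal(icer(10, -0.01)$label, "control-dominant")
  expect_equal(icer(100, 0)$label, "indeterminate")
  expect_equal(icer(100, 1e-12)$label, "indeterminate")
  expect_equal(icer(-100, -0.01)$label, "ratio")  # southwest trade-off
})

test_that("net monetary benefit is linear with the break-even identity", {
  expect_equal(nmb(155.45, 0.008, 37530), 37530 * 0.008 - 155.45)
  expect_equal(round(nmb(155.45, 0.008, 37530), 2), 144.79)
  expect_equal(nmb(150, 0.01, 150 / 0.01), 0)
  expect_equal(nmb(155.45, 0.008, 0), -155.45)
  expect_error(nmb(1, 1, -5), "lambda")
})

test_that("degenerate resampling returns the point estimate everywhere", {
  d <- data.frame(arm = rep(c("intervention", "control"), each = 5),
                  cost = rep(c(100, 50), each = 5),
                  qaly = rep(c(0.4, 0.38), each = 5),
                  endocrine_therapy = 0, baseline_utility = 0.6)
  draws <- bootstrap_cea(d, B = 50, seed = 1)
  expect_true(all(draws$delta_cost == 50))
  expect_true(all(abs(draws$delta_qaly - 0.02) < 1e-12))
  expect_equal(unname(bca_interval(draws$delta_cost, 50)), c(50, 50))
  expect_error(bootstrap_cea(d[d$arm == "control", ], B = 10), "2 participants")
})

test_that("bootstrap draws are reproducible and scale with B", {
  d <- synthetic_cohort(n_per_arm = 30, seed = 5)
  d1 <- bootstrap_cea(d, B = 200, seed = 9)
  d2 <- bootstrap_cea(d, B = 200, seed = 9)
  expect_identical(d1, d2)
  d3 <- bootstrap_cea(d, B = 400, seed = 9)
  expect_equal(attr(d1, "point"), attr(d3, "point"))  # point is B-free
  expect_equal(nrow(d3), 400)
})

test_that("BCa reduces to the percentile interval for symmetric draws", {
  set.seed(11)
  draws <- rnorm(20000, 5, 1)
  ci <- bca_interval(draws, 5, jackknife = NULL)
  pct <- quantile(draws, c(0.025, 0.975), names = FALSE)
  expect_lt(abs(ci[1] - pct[1]), 0.05)
  expect_lt(abs(ci[2] - pct[2]), 0.05)
})

test_that("BCa matches the reference implementation on a small instance", {
  skip_if_not_installed("boot")
  set.seed(12)
  x <- rexp(10)  # skewed so z0 and a both matter
  b <- boot::boot(x, function(d, i) mean(d[i]), R = 2000)
  ref <- boot::boot.ci(b, type = "bca")$bca[4:5]
  jack <- vapply(seq_along(x), function(i) mean(x[-i]), numeric(1))
  mine <- bca_interval(as.vector(b$t), b$t0, jackknife = jack)
  expect_equal(unname(mine), ref, tolerance = 1e-6)
})

test_that("BCa intervals attain nominal coverage for a known QALY gain", {
  covered <- vapply(seq_len(200), function(r) {
    d <- synthetic_cohort(n_per_arm = 96, delta_cost = 0,
                          delta_qaly = 0.01, seed = 8000 + r)
    draws <- bootstrap_cea(d, B = 1000, seed = 9000 + r)
    point <- attr(draws, "point")
    jack <- vapply(seq_len(nrow(d)), function(i)
      trialcea:::cea_point(d[-i, , drop = FALSE], TRUE)[["delta_qaly"]],
      numeric(1))
    ci <- bca_interval(draws$delta_qaly, point[["delta_qaly"]], jack)
    ci[1] <= 0.01 && 0.01 <= ci[2]
  }, logical(1))
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("CE-plane proportions partition the draws", {
  one <- data.frame(delta_cost = 1, delta_qaly = 1)
  expect_equal(ce_plane(one), c(NE = 1, SE = 0, SW = 0, NW = 0))
  four <- data.frame(delta_cost = c(1, 1, -1, -1),
                     delta_qaly = c(1, -1, -1, 1))
  expect_equal(unname(ce_plane(four)), rep(0.25, 4))
  set.seed(13)
  rand <- data.frame(delta_cost = c(rnorm(50), 0, 0),
                     delta_qaly = c(rnorm(50), 0, 1))
  expect_equal(sum(ce_plane(rand)), 1)
  origin <- data.frame(delta_cost = 0, delta_qaly = 0)
  expect_equal(unname(ce_plane(origin)), rep(0.25, 4))
})

test_that("the CEAC hits its analytic limits and enumerated values", {
  draws <- data.frame(delta_cost = c(100, -50, 300),
                      delta_qaly = c(0.01, 0.002, -0.001))
  cv <- ceac(draws, c(0, 37530, 1e9))
  expect_equal(cv$probability[1], mean(draws$delta_cost < 0))  # 1/3
  expect_equal(cv$probability[2], 2 / 3)
  expect_equal(cv$probability[3], mean(draws$delta_qaly > 0))  # 2/3
  expect_true(all(cv$probability >= 0 & cv$probability <= 1))
  expect_error(ceac(draws, numeric(0)), "lambda_grid")
})

test_that("the full evaluation is internally consistent", {
  d <- synthetic_cohort(n_per_arm = 60, delta_cost = 100,
                        delta_qaly = 0.01, seed = 14)
  res <- cea_evaluate(d, B = 500, seed = 15, lambda_grid = c(0, 20000, 50000))
  expect_equal(sum(res$quadrants), 1)
  # NMB at the ICER's own ratio is zero for the point estimate
  if (res$icer$label == "ratio")
    expect_equal(nmb(res$delta_cost, res$delta_qaly, res$icer$value), 0,
                 tolerance = 1e-9)
  # point-estimate quadrant agrees with the ICER label
  if (res$delta_qaly > 0 && res$delta_cost > 0)
    expect_equal(res$icer$label, "ratio")
  expect_equal(res$prob_ce_at_threshold,
               mean(nmb(res$draws$delta_cost, res$draws$delta_qaly,
                        res$threshold) > 0))
  res2 <- cea_evaluate(d, B = 500, seed = 15,
                       lambda_grid = c(0, 20000, 50000))
  expect_identical(res$draws, res2$draws)
  expect_identical(res$bca_ci_qaly, res2$bca_ci_qaly)
})
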