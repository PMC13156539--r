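#' Incremental cost-effectiveness ratio with dominance labelling
#'
#' Labels the (incremental cost, incremental effect) point: a positive
#' ratio when both increments are positive (northeast) or both negative
#' (southwest trade-off), `"intervention-dominant"` when the intervention
#' is more effective and no more costly, `"control-dominant"` when it is
#' less effective and no cheaper, and `"indeterminate"` when the QALY
#' increment is below `epsilon` in magnitude (report net monetary benefit
#' instead of a ratio).
#'
#' @param delta_cost incremental cost (US$, intervention minus control).
#' @param delta_qaly incremental effect (QALYs).
#' @param epsilon magnitude below which the effect difference is treated
#'   as zero.
#' @return List with `label` and `value` (the ratio, or `NA`).
#' @examples
#' icer(155.45, 0.008)$value  # 19431.25
#' @export
icer <- function(delta_cost, delta_qaly, epsilon = 1e-9) {
  stopifnot(is.finite(delta_cost), is.finite(delta_qaly))
  if (abs(delta_qaly) < epsilon)
    return(list(label = "indeterminate", value = NA_real_))
  if (delta_qaly > 0 && delta_cost <= 0)
    return(list(label = "intervention-dominant", value = NA_real_))
  if (delta_qaly < 0 && delta_cost >= 0)
    return(list(label = "control-dominant", value = NA_real_))
  list(label = "ratio", value = delta_cost / delta_qaly)
}

#' Net monetary benefit
#'
#' `lambda * delta_qaly - delta_cost`: positive exactly when the
#' intervention is cost-effective at willingness-to-pay `lambda`.
#'
#' @param delta_cost incremental cost (US$).
#' @param delta_qaly incremental effect (QALYs).
#' @param lambda willingness-to-pay threshold (US$/QALY, >= 0).
#' @return US$.
#' @examples
#' nmb(155.45, 0.008, 37530)
#' @export
nmb <- function(delta_cost, delta_qaly, lambda) {
  if (any(lambda < 0)) stop("lambda must be >= 0", call. = FALSE)
  lambda * delta_qaly - delta_cost
}

# adjusted (or raw) incremental cost and QALYs for one dataset
cea_point <- function(d, adjusted = TRUE) {
  g <- as.numeric(d$arm == "intervention")
  if (!adjusted) {
    return(c(delta_cost = mean(d$cost[g == 1]) - mean(d$cost[g == 0]),
             delta_qaly = mean(d$qaly[g == 1]) - mean(d$qaly[g == 0])))
  }
  Xc <- cbind(1, g, d$endocrine_therapy)
  Xq <- cbind(Xc, d$baseline_utility)
  c(delta_cost = unname(stats::lm.fit(Xc, d$cost)$coefficients[2]),
    delta_qaly = unname(stats::lm.fit(Xq, d$qaly)$coefficients[2]))
}

#' Stratified bootstrap of incremental costs and QALYs
#'
#' Resamples participants with replacement within arm (preserving the
#' trial's 1:1 design) and recomputes the covariate-adjusted incremental
#' cost and incremental QALYs per replicate. With a list of per-imputation
#' datasets the replications are divided evenly across the completed
#' datasets and the draws concatenated, so imputation uncertainty
#' propagates into the bootstrap distribution.
#'
#' @param data data frame with columns `arm`, `cost`, `qaly`,
#'   `endocrine_therapy`, `baseline_utility` (the latter two only needed
#'   when `adjusted`), or a list of such data frames (one per
#'   imputation).
#' @param B total bootstrap replications.
#' @param seed integer seed.
#' @param adjusted use covariate-adjusted arm contrasts (default) or raw
#'   mean differences.
#' @return A `cea_draws` data frame of `B` rows (`delta_cost`,
#'   `delta_qaly`) with the pooled point estimate as attribute `point`.
#' @export
bootstrap_cea <- function(data, B = 10000, seed = 1L, adjusted = TRUE) {
  datasets <- if (is.data.frame(data)) list(data) else data
  if (B < 1) stop("B must be >= 1", call. = FALSE)
  for (d in datasets) {
    n_arm <- table(factor(d$arm, levels = c("intervention", "control")))
    if (min(n_arm) < 2)
      stop("need at least 2 participants per arm", call. = FALSE)
  }
  m <- length(datasets)
  b_each <- rep(B %/% m, m)
  if (B %% m) b_each[seq_len(B %% m)] <- b_each[seq_len(B %% m)] + 1
  set.seed(seed)
  draws <- vector("list", m)
  for (k in seq_len(m)) {
    d <- datasets[[k]]
    idx_by_arm <- split(seq_len(nrow(d)), d$arm)
    reps <- matrix(NA_real_, b_each[k], 2)
    for (b in seq_len(b_each[k])) {
      take <- unlist(lapply(idx_by_arm, function(ii)
        ii[sample.int(length(ii), length(ii), replace = TRUE)]),
        use.names = FALSE)
      reps[b, ] <- cea_point(d[take, , drop = FALSE], adjusted)
    }
    draws[[k]] <- reps
  }
  out <- as.data.frame(do.call(rbind, draws))
  names(out) <- c("delta_cost", "delta_qaly")
  pts <- vapply(datasets, cea_point, numeric(2), adjusted = adjusted)
  attr(out, "point") <- rowMeans(pts)
  attr(out, "seed") <- seed
  attr(out, "B") <- B
  class(out) <- c("cea_draws", "data.frame")
  out
}

#' Bias-corrected and accelerated bootstrap interval
#'
#' Standard BCa: the bias correction `z0` is the normal quantile of the
#' fraction of draws below the point estimate, the acceleration `a` is
#' the jackknife skewness
#' `sum((mean(j) - j)^3) / (6 * sum((mean(j) - j)^2)^1.5)`, and the
#' interval takes the bootstrap distribution at the adjusted quantiles
#' with normal-score interpolation between order statistics.
#'
#' @param draws bootstrap replicate values of the statistic.
#' @param point the point estimate on the full data.
#' @param jackknife leave-one-out estimates (for the acceleration);
#'   `NULL` sets `a = 0` (the bias-corrected percentile interval).
#' @param conf confidence level.
#' @return `c(low, high)`. All draws identical gives the degenerate
#'   interval `(c, c)`.
#' @export
bca_interval <- function(draws, point, jackknife = NULL, conf = 0.95) {
  draws <- draws[is.finite(draws)]
  B <- length(draws)
  if (B < 1) stop("no draws", call. = FALSE)
  if (max(draws) - min(draws) < .Machine$double.eps * max(1, abs(point)))
    return(c(low = draws[1], high = draws[1]))
  prop <- mean(draws < point)
  prop <- min(max(prop, 1 / (B + 1)), B / (B + 1))
  z0 <- stats::qnorm(prop)
  a <- 0
  if (!is.null(jackknife) && length(jackknife) > 2) {
    u <- mean(jackknife) - jackknife
    denom <- sum(u^2)^1.5
    if (denom > 0) a <- sum(u^3) / (6 * denom)
  }
  alpha <- c((1 - conf) / 2, (1 + conf) / 2)
  zalpha <- stats::qnorm(alpha)
  adj <- stats::pnorm(z0 + (z0 + zalpha) / (1 - a * (z0 + zalpha)))
  sorted <- sort(draws)
  ends <- vapply(adj, function(p) {
    # normal-score interpolation between adjacent order statistics
    h <- (B + 1) * p
    if (h <= 1) return(sorted[1])
    if (h >= B) return(sorted[B])
    k <- floor(h)
    g1 <- stats::qnorm(k / (B + 1)); g2 <- stats::qnorm((k + 1) / (B + 1))
    w <- (stats::qnorm(p) - g1) / (g2 - g1)
    (1 - w) * sorted[k] + w * sorted[k + 1]
  }, numeric(1))
  c(low = ends[1], high = ends[2])
}

#' Cost-effectiveness plane quadrant proportions
#'
#' Fractions of bootstrap draws in each quadrant of the (delta QALY,
#' delta cost) plane: NE more effective/more costly, SE more
#' effective/cheaper (dominant), SW less effective/cheaper, NW less
#' effective/more costly (dominated). Draws on a boundary are split
#' equally between the two adjacent quadrants (a draw at the origin
#' counts 1/4 to each).
#'
#' @param draws a `cea_draws` data frame (columns `delta_cost`,
#'   `delta_qaly`).
#' @return Named numeric vector `(NE, SE, SW, NW)` summing to 1.
#' @export
ce_plane <- function(draws) {
  if (nrow(draws) == 0) stop("no draws", call. = FALSE)
  e_pos <- (draws$delta_qaly > 0) + 0.5 * (draws$delta_qaly == 0)
  c_pos <- (draws$delta_cost > 0) + 0.5 * (draws$delta_cost == 0)
  c(NE = mean(e_pos * c_pos),
    SE = mean(e_pos * (1 - c_pos)),
    SW = mean((1 - e_pos) * (1 - c_pos)),
    NW = mean((1 - e_pos) * c_pos))
}

#' Cost-effectiveness acceptability curve
#'
#' For each willingness-to-pay value, the fraction of bootstrap draws
#' with positive net monetary benefit. At `lambda = 0` this is the
#' probability the intervention saves money; as `lambda` grows it tends
#' to the probability the intervention gains QALYs.
#'
#' @param draws a `cea_draws` data frame.
#' @param lambda_grid willingness-to-pay values (US$/QALY, >= 0).
#' @return Data frame with columns `lambda`, `probability`.
#' @export
ceac <- function(draws, lambda_grid = seq(0, 200000, by = 500)) {
  if (length(lambda_grid) == 0 || any(lambda_grid < 0))
    stop("lambda_grid must be non-empty and >= 0", call. = FALSE)
  prob <- vapply(lambda_grid, function(l)
    mean(nmb(draws$delta_cost, draws$delta_qaly, l) > 0), numeric(1))
  data.frame(lambda = lambda_grid, probability = prob)
}

#' Full bootstrap cost-effectiveness evaluation
#'
#' Point incremental cost and QALYs (covariate-adjusted, pooled over
#' imputations), the ICER/dominance label, net monetary benefit at the
#' decision threshold, stratified bootstrap draws with BCa intervals for
#' both increments, cost-effectiveness plane quadrant proportions, the
#' acceptability curve, and the probability of cost-effectiveness at the
#' threshold.
#'
#' The acceleration of the BCa intervals is computed from the jackknife
#' on the first (or only) completed dataset.
#'
#' @inheritParams bootstrap_cea
#' @param lambda_grid CEAC willingness-to-pay grid.
#' @param threshold decision threshold (US$/QALY).
#' @return A `cea_result` list.
#' @export
cea_evaluate <- function(data, B = 10000, seed = 1L,
                         lambda_grid = seq(0, 200000, by = 500),
                         threshold = 37530, adjusted = TRUE) {
  draws <- bootstrap_cea(data, B = B, seed = seed, adjusted = adjusted)
  point <- attr(draws, "point")
  d1 <- if (is.data.frame(data)) data else data[[1]]
  jack <- vapply(seq_len(nrow(d1)), function(i)
    cea_point(d1[-i, , drop = FALSE], adjusted), numeric(2))
  ic <- icer(point[["delta_cost"]], point[["delta_qaly"]])
  curve <- ceac(draws, lambda_grid)
  structure(list(
    delta_cost = point[["delta_cost"]],
    delta_qaly = point[["delta_qaly"]],
    icer = ic,
    nmb = nmb(point[["delta_cost"]], point[["delta_qaly"]], threshold),
    bca_ci_cost = bca_interval(draws$delta_cost, point[["delta_cost"]],
                               jack[1, ]),
    bca_ci_qaly = bca_interval(draws$delta_qaly, point[["delta_qaly"]],
                               jack[2, ]),
    quadrants = ce_plane(draws),
    ceac = curve,
    prob_ce_at_threshold = mean(nmb(draws$delta_cost, draws$delta_qaly,
                                    threshold) > 0),
    threshold = threshold,
    draws = draws, B = attr(draws, "B"), seed = seed),
    class = "cea_result")
}

#' @export
print.cea_result <- function(x, ...) {
  cat("<cea_result>\n")
  cat(sprintf("  incremental cost US$%.2f; incremental QALYs %.4f\n",
              x$delta_cost, x$delta_qaly))
  lab <- if (x$icer$label == "ratio")
    sprintf("US$%.2f per QALY", x$icer$value) else x$icer$label
  cat(sprintf("  ICER: %s; NMB at US$%s: %.2f\n", lab,
              format(x$threshold, big.mark = ","), x$nmb))
  cat(sprintf("  95%% BCa cost (%.2f, %.2f); QALY (%.4f, %.4f)  [B = %d]\n",
              x$bca_ci_cost[1], x$bca_ci_cost[2],
              x$bca_ci_qaly[1], x$bca_ci_qaly[2], x$B))
  cat(sprintf("  CE plane: NE %.2f, SE %.2f, SW %.2f, NW %.2f\n",
              x$quadrants["NE"], x$quadrants["SE"], x$quadrants["SW"],
              x$quadrants["NW"]))
  cat(sprintf("  P(cost-effective at threshold) = %.2f\n",
              x$prob_ce_at_threshold))
  invisible(x)
}

#' Per-participant cost and QALY inputs for the CEA
#'
#' Combines [cost_breakdown()] and [participant_qalys()] into the
#' participant-level table the bootstrap resamples. For an
#' `imputation_set`, returns one table per completed panel.
#'
#' @param x a completed `outcome_panel` or an `imputation_set`.
#' @param cost_params list as in [default_cost_params()].
#' @return A data frame (or list of data frames) with columns `arm`,
#'   `endocrine_therapy`, `baseline_utility`, `cost`, `qaly`.
#' @export
participant_cea_data <- function(x, cost_params = default_cost_params()) {
  one <- function(panel) {
    costs <- cost_breakdown(panel, cost_params)
    q <- participant_qalys(panel)
    d <- merge(costs, q[, c("participant_id", "baseline_utility", "qaly")],
               by = "participant_id", sort = FALSE)
    data.frame(participant_id = d$participant_id, arm = d$arm,
               endocrine_therapy = d$endocrine_therapy,
               baseline_utility = d$baseline_utility,
               cost = d$total, qaly = d$qaly, stringsAsFactors = FALSE)
  }
  if (inherits(x, "imputation_set")) lapply(x$panels, one) else one(x)
}
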