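#' Gaussian estimating equations with an exchangeable working correlation
#'
#' Solves the identity-link estimating equations for clustered continuous
#' responses, iterating between the generalized-least-squares update of
#' the coefficients and moment estimation of the exchangeable working
#' correlation, and reports the robust (sandwich) covariance alongside
#' the model-based one. This is the low-level solver behind
#' [fit_gee()]; it accepts an arbitrary design matrix.
#'
#' @param y numeric response vector.
#' @param X design matrix (including the intercept).
#' @param id cluster identifier, one per row.
#' @param corstr `"exchangeable"` or `"independence"`.
#' @param tol convergence tolerance on the maximum coefficient change.
#' @param max_iter iteration cap; non-convergence is flagged, not fatal.
#' @return List with `beta`, `vcov_robust`, `vcov_naive`, `alpha`,
#'   `sigma2`, `n_clusters`, `converged`, `iterations`.
#' @export
gee_exchangeable <- function(y, X, id,
                             corstr = c("exchangeable", "independence"),
                             tol = 1e-8, max_iter = 100) {
  corstr <- match.arg(corstr)
  X <- as.matrix(X)
  p <- ncol(X)
  n_obs <- length(y)
  if (nrow(X) != n_obs || length(id) != n_obs)
    stop("y, X and id must have matching lengths", call. = FALSE)
  idx <- split(seq_len(n_obs), id)
  sizes <- lengths(idx)
  n_pairs <- sum(sizes * (sizes - 1) / 2)
  max_t <- max(sizes)

  beta <- qr.coef(qr(X), y)
  alpha <- 0
  sigma2 <- NA_real_
  converged <- FALSE
  it <- 0
  while (it < max_iter) {
    it <- it + 1
    r <- as.vector(y - X %*% beta)
    sigma2 <- sum(r^2) / (n_obs - p)
    if (corstr == "exchangeable" && n_pairs > p) {
      num <- sum(vapply(idx, function(ii) {
        ri <- r[ii]
        (sum(ri)^2 - sum(ri^2)) / 2
      }, numeric(1)))
      alpha <- num / ((n_pairs - p) * sigma2)
      lo <- if (max_t > 1) -1 / (max_t - 1) + 1e-6 else 0
      alpha <- min(max(alpha, lo), 1 - 1e-6)
    }
    A <- matrix(0, p, p)
    b <- numeric(p)
    for (ii in idx) {
      Xi <- X[ii, , drop = FALSE]
      ni <- length(ii)
      Ri <- matrix(alpha, ni, ni); diag(Ri) <- 1
      Vinv <- chol2inv(chol(Ri)) / sigma2
      A <- A + crossprod(Xi, Vinv %*% Xi)
      b <- b + crossprod(Xi, Vinv %*% y[ii])
    }
    beta_new <- solve(A, b)
    delta <- max(abs(beta_new - beta))
    beta <- as.vector(beta_new)
    if (delta < tol) { converged <- TRUE; break }
  }

  # sandwich: A^{-1} (sum_i X_i' V_i^{-1} r_i r_i' V_i^{-1} X_i) A^{-1}
  A <- matrix(0, p, p)
  B <- matrix(0, p, p)
  for (ii in idx) {
    Xi <- X[ii, , drop = FALSE]
    ni <- length(ii)
    Ri <- matrix(alpha, ni, ni); diag(Ri) <- 1
    Vinv <- chol2inv(chol(Ri)) / sigma2
    A <- A + crossprod(Xi, Vinv %*% Xi)
    ui <- crossprod(Xi, Vinv %*% (y[ii] - Xi %*% beta))
    B <- B + tcrossprod(ui)
  }
  Ainv <- solve(A)
  vr <- Ainv %*% B %*% Ainv
  vr <- (vr + t(vr)) / 2
  names(beta) <- colnames(X)
  dimnames(vr) <- dimnames(Ainv) <- list(colnames(X), colnames(X))
  list(beta = beta, vcov_robust = vr, vcov_naive = Ainv, alpha = alpha,
       sigma2 = sigma2, n_clusters = length(idx), converged = converged,
       iterations = it)
}

gee_design <- function(panel, outcome) {
  tp <- unique(panel$timepoint)
  if (length(tp) != 3)
    stop("the effectiveness model expects three timepoints", call. = FALSE)
  d <- as.data.frame(panel)
  base <- d[d$timepoint == tp[1], c("participant_id", outcome)]
  names(base)[2] <- "baseline"
  if (anyNA(base$baseline))
    stop("baseline `", outcome, "` must be present for all participants",
         call. = FALSE)
  fu <- d[d$timepoint %in% tp[-1], ]
  fu <- merge(fu, base, by = "participant_id", sort = FALSE)
  fu <- fu[!is.na(fu[[outcome]]), ]
  fu <- fu[order(fu$participant_id, fu$timepoint), ]
  X <- cbind(intercept = 1,
             group = as.integer(fu$arm == "intervention"),
             t2 = as.integer(fu$timepoint == tp[3]),
             group_t2 = as.integer(fu$arm == "intervention" &
                                     fu$timepoint == tp[3]),
             endocrine = fu$endocrine_therapy,
             baseline = fu$baseline)
  list(y = fu[[outcome]], X = X, id = fu$participant_id,
       covariate_means = c(endocrine = mean(d$endocrine_therapy[
         d$timepoint == tp[1]]), baseline = mean(base$baseline)),
       timepoints = tp)
}

baseline_arm_stats <- function(panel, outcome) {
  tp <- unique(panel$timepoint)[1]
  d <- as.data.frame(panel)
  base <- d[d$timepoint == tp, ]
  out <- lapply(split(base[[outcome]], base$arm), function(v)
    c(mean = mean(v), sd = stats::sd(v), n = length(v)))
  out
}

#' Fit the adjusted repeated-measures effectiveness model
#'
#' Models the T1 and T2 responses with group, a T2 indicator, their
#' interaction, endocrine therapy and the baseline score as covariates,
#' solved by Gaussian estimating equations with an exchangeable working
#' correlation and robust (sandwich) standard errors. The baseline
#' assessment enters as a covariate rather than as a response: that is
#' the only parameterization in which a single "group difference at T1"
#' and "at T2" is defined while adjusting for baseline outcomes.
#'
#' When given an [impute_panel()] result the model is fitted on each
#' completed panel; [group_contrast()] then pools by Rubin's rules.
#'
#' @param x an `outcome_panel` or an `imputation_set`.
#' @param outcome instrument column name (e.g. `"sis"`).
#' @param corstr working correlation for the solver.
#' @return A `gee_fit` (single panel) or `gee_fit` with `m > 1`
#'   (imputation set), holding per-imputation solver results.
#' @examples
#' cfg <- trial_config(n_per_arm = 30, seed = 11)
#' fit <- fit_gee(generate_trial(cfg), "sis")
#' group_contrast(fit, "T1")
#' @export
fit_gee <- function(x, outcome, corstr = "exchangeable") {
  panels <- if (inherits(x, "imputation_set")) x$panels else list(x)
  src <- if (inherits(x, "imputation_set")) x$source else x
  fits <- lapply(panels, function(p) {
    des <- gee_design(p, outcome)
    f <- gee_exchangeable(des$y, des$X, des$id, corstr = corstr)
    f$covariate_means <- des$covariate_means
    f$timepoints <- des$timepoints
    f
  })
  structure(list(outcome = outcome, m = length(fits), fits = fits,
                 baseline_stats = baseline_arm_stats(src, outcome),
                 timepoints = fits[[1]]$timepoints,
                 converged = all(vapply(fits, `[[`, logical(1), "converged"))),
            class = "gee_fit")
}

#' @export
print.gee_fit <- function(x, ...) {
  f <- x$fits[[1]]
  cat(sprintf("<gee_fit> outcome %s; %d clusters; alpha %.3f; m = %d%s\n",
              x$outcome, f$n_clusters, f$alpha, x$m,
              if (x$converged) "" else " [NOT CONVERGED]"))
  if (x$m == 1) print(round(f$beta, 4))
  invisible(x)
}

contrast_vector <- function(fit, timepoint) {
  tp <- fit$timepoints
  p <- length(fit$fits[[1]]$beta)
  L <- numeric(p)
  names(L) <- names(fit$fits[[1]]$beta)
  L["group"] <- 1
  if (identical(timepoint, tp[3])) {
    L["group_t2"] <- 1
  } else if (!identical(timepoint, tp[2])) {
    stop("unknown timepoint `", timepoint, "`; contrasts exist at ",
         tp[2], " and ", tp[3], call. = FALSE)
  }
  L
}

#' Adjusted between-group contrast at a follow-up timepoint
#'
#' Extracts the intervention-minus-control adjusted mean difference (the
#' group main effect, plus the group x T2 interaction at T2) with its
#' robust 95% CI, the Bonferroni-adjusted p value over `k_comparisons`
#' pairwise comparisons, Cohen's d (contrast divided by the pooled
#' unadjusted baseline SD) and the half-baseline-SD minimal important
#' clinical difference flag. Estimates from multiply imputed fits are
#' pooled by Rubin's rules with t-based inference on Rubin's degrees of
#' freedom.
#'
#' @param fit a [fit_gee()] result.
#' @param timepoint follow-up label (e.g. `"T1"`).
#' @param k_comparisons Bonferroni family size (default 2: the two
#'   follow-up contrasts per outcome).
#' @param conf confidence level.
#' @return A `contrast_result` list.
#' @export
group_contrast <- function(fit, timepoint, k_comparisons = 2, conf = 0.95) {
  if (!fit$converged)
    stop("cannot extract contrasts from a non-converged fit", call. = FALSE)
  L <- contrast_vector(fit, timepoint)
  est <- vapply(fit$fits, function(f) sum(L * f$beta), numeric(1))
  vr <- vapply(fit$fits, function(f)
    as.numeric(t(L) %*% f$vcov_robust %*% L), numeric(1))
  pooled <- pool_rubin(est, vr)
  q <- if (is.finite(pooled$df)) stats::qt((1 + conf) / 2, pooled$df)
       else stats::qnorm((1 + conf) / 2)
  stat <- pooled$point / pooled$se
  p_raw <- if (is.finite(pooled$df)) 2 * stats::pt(-abs(stat), pooled$df)
           else 2 * stats::pnorm(-abs(stat))
  bs <- fit$baseline_stats
  sd_pool <- pooled_baseline_sd(bs$intervention["sd"], bs$control["sd"],
                                bs$intervention["n"], bs$control["n"])
  d <- cohens_d(pooled$point, sd_pool)
  thr <- micd(sd_pool)
  structure(list(outcome = fit$outcome, timepoint = timepoint,
                 estimate = pooled$point, se = pooled$se,
                 ci = c(pooled$point - q * pooled$se,
                        pooled$point + q * pooled$se),
                 df = pooled$df, p_raw = p_raw,
                 p_bonferroni = min(1, k_comparisons * p_raw),
                 k_comparisons = k_comparisons,
                 cohen_d = d, micd = thr,
                 exceeds_micd = abs(pooled$point) > thr,
                 pooled = pooled),
            class = "contrast_result")
}

#' @export
print.contrast_result <- function(x, ...) {
  cat(sprintf(
    "<contrast_result> %s at %s: %.2f (95%% CI %.2f to %.2f), p = %.3g, d = %.2f%s\n",
    x$outcome, x$timepoint, x$estimate, x$ci[1], x$ci[2], x$p_bonferroni,
    x$cohen_d, if (x$exceeds_micd) " [exceeds MICD]" else ""))
  invisible(x)
}

#' Covariate-adjusted group means at a timepoint
#'
#' Model-predicted mean per arm with covariates held at their sample
#' means, pooled across imputations.
#'
#' @param fit a [fit_gee()] result.
#' @param timepoint follow-up label.
#' @return Data frame with one row per arm: mean and robust SE.
#' @export
adjusted_means <- function(fit, timepoint) {
  tp <- fit$timepoints
  is_t2 <- identical(timepoint, tp[3])
  if (!is_t2 && !identical(timepoint, tp[2]))
    stop("unknown timepoint `", timepoint, "`", call. = FALSE)
  rows <- lapply(c(intervention = 1, control = 0), function(g) {
    ests <- vapply(fit$fits, function(f) {
      xv <- c(1, g, as.integer(is_t2), g * as.integer(is_t2),
              f$covariate_means["endocrine"], f$covariate_means["baseline"])
      sum(xv * f$beta)
    }, numeric(1))
    vars <- vapply(fit$fits, function(f) {
      xv <- c(1, g, as.integer(is_t2), g * as.integer(is_t2),
              f$covariate_means["endocrine"], f$covariate_means["baseline"])
      as.numeric(t(xv) %*% f$vcov_robust %*% xv)
    }, numeric(1))
    pooled <- pool_rubin(ests, vars)
    c(mean = pooled$point, se = pooled$se)
  })
  out <- as.data.frame(do.call(rbind, rows))
  out$arm <- rownames(out)
  rownames(out) <- NULL
  out[, c("arm", "mean", "se")]
}

#' Pooled unadjusted baseline standard deviation
#'
#' The two-sample pooled SD,
#' `sqrt(((n_a - 1) sd_a^2 + (n_b - 1) sd_b^2) / (n_a + n_b - 2))`,
#' used as the denominator of Cohen's d and the basis of the MICD.
#'
#' @param sd_a,sd_b per-arm baseline SDs (> 0).
#' @param n_a,n_b per-arm sample sizes (>= 2).
#' @return The pooled SD.
#' @examples
#' pooled_baseline_sd(9.09, 9.93, 96, 96)
#' @export
pooled_baseline_sd <- function(sd_a, sd_b, n_a, n_b) {
  if (any(c(sd_a, sd_b) <= 0)) stop("SDs must be > 0", call. = FALSE)
  if (any(c(n_a, n_b) < 2)) stop("need n >= 2 per arm", call. = FALSE)
  unname(sqrt(((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)))
}

#' Cohen's d from an adjusted mean difference
#'
#' The adjusted between-group mean difference divided by the pooled
#' unadjusted baseline SD.
#'
#' @param adjusted_mean_difference contrast on the score scale.
#' @param pooled_sd pooled baseline SD (> 0).
#' @return The standardized effect size.
#' @examples
#' cohens_d(-7.79, pooled_baseline_sd(9.09, 9.93, 96, 96))
#' @export
cohens_d <- function(adjusted_mean_difference, pooled_sd) {
  if (pooled_sd <= 0) stop("pooled_sd must be > 0", call. = FALSE)
  adjusted_mean_difference / pooled_sd
}

#' Distribution-based minimal important clinical difference
#'
#' One-half the baseline SD.
#'
#' @param baseline_sd baseline SD (> 0).
#' @return The MICD threshold on the score scale.
#' @examples
#' micd(9.50)  # 4.75
#' @export
micd <- function(baseline_sd) {
  if (baseline_sd <= 0) stop("baseline_sd must be > 0", call. = FALSE)
  0.5 * baseline_sd
}

#' Table of adjusted contrasts for several outcomes
#'
#' Runs [fit_gee()] and [group_contrast()] per outcome and follow-up
#' timepoint and assembles the results in one data frame (adjusted means
#' with SE per arm, difference with robust CI, Bonferroni-adjusted p,
#' Cohen's d, MICD flag).
#'
#' @param x an `outcome_panel` or `imputation_set`.
#' @param outcomes instrument column names.
#' @param k_comparisons Bonferroni family size.
#' @return Data frame with one row per outcome x timepoint.
#' @export
effects_table <- function(x, outcomes = c("bis", "sis", "psqi", "mspss",
                                          "pcs", "mcs"),
                          k_comparisons = 2) {
  rows <- list()
  for (oc in outcomes) {
    fit <- fit_gee(x, oc)
    for (tp in fit$timepoints[-1]) {
      ct <- group_contrast(fit, tp, k_comparisons = k_comparisons)
      am <- adjusted_means(fit, tp)
      rows[[length(rows) + 1]] <- data.frame(
        outcome = oc, timepoint = tp,
        mean_intervention = am$mean[am$arm == "intervention"],
        se_intervention = am$se[am$arm == "intervention"],
        mean_control = am$mean[am$arm == "control"],
        se_control = am$se[am$arm == "control"],
        difference = ct$estimate, ci_low = ct$ci[1], ci_high = ct$ci[2],
        p_raw = ct$p_raw, p_bonferroni = ct$p_bonferroni,
        cohen_d = ct$cohen_d, micd = ct$micd,
        exceeds_micd = ct$exceeds_micd, stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
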