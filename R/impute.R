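#' Multiple imputation of missing follow-up values
#'
#' Creates `m` completed copies of a panel whose only missingness is in
#' the T1/T2 analysis variables (instrument scores and utility), as left
#' by [apply_missingness()]. Two engines are provided:
#'
#' * `"chained"` (default): per-instrument chained equations with
#'   predictive-mean matching (PMM). Each follow-up value is modelled on
#'   arm, endocrine therapy, the instrument's baseline score and the
#'   other follow-up assessment; regression parameters are drawn from
#'   their approximate Bayesian posterior, predicted values are matched
#'   to the `donors` nearest observed cases and one donor's observed
#'   value is copied. PMM keeps imputations on the observed support, so
#'   scale totals stay integer and in range.
#' * `"mcmc"`: a joint multivariate-normal draw. With monotone dropout
#'   the joint normal factorizes sequentially (T1 given baseline, then
#'   T2 given baseline and T1), and values are drawn from those
#'   conditional normals with posterior-drawn parameters, then clipped
#'   to the instrument range. This is the sensitivity-analysis variant.
#'
#' Non-missing cells are never altered.
#'
#' @param panel an `outcome_panel` with complete baseline rows.
#' @param m number of imputations (>= 1).
#' @param method `"chained"` or `"mcmc"`.
#' @param seed integer seed; imputation `j` uses `child_seed(seed, "imp j")`.
#' @param n_iter chained-equation cycles per imputation.
#' @param donors PMM donor-pool size.
#' @return An `imputation_set`: list with elements `m`, `method`, `seed`,
#'   and `panels` (list of completed `outcome_panel`s).
#' @examples
#' cfg <- trial_config(n_per_arm = 15, seed = 3)
#' panel <- apply_missingness(generate_trial(cfg), 0.2, "MCAR", seed = 4)
#' imps <- impute_panel(panel, m = 2, seed = 5)
#' length(imps$panels)
#' @export
impute_panel <- function(panel, m = 20, method = c("chained", "mcmc"),
                         seed = 1L, n_iter = 5, donors = 5) {
  method <- match.arg(method)
  if (m < 1) stop("`m` must be >= 1", call. = FALSE)
  tp <- unique(panel$timepoint)
  # participant-major order so per-timepoint slices align row by row
  panel <- panel[order(panel$participant_id, match(panel$timepoint, tp)), ]
  rownames(panel) <- NULL
  vars <- panel_instruments(panel)
  base <- panel[panel$timepoint == tp[1], ]
  if (anyNA(as.data.frame(base)[vars]))
    stop("baseline values must not be missing (violates the study design)",
         call. = FALSE)
  if (length(tp) != 3)
    stop("imputation expects three timepoints", call. = FALSE)

  any_missing <- anyNA(as.data.frame(panel)[vars])
  panels <- vector("list", m)
  for (j in seq_len(m)) {
    if (!any_missing) {
      panels[[j]] <- panel
      next
    }
    set.seed(child_seed(seed, paste("imp", j)))
    done <- panel
    for (v in vars) {
      params <- instrument_range(v, panel)
      wide <- panel_to_wide(panel, v, tp)
      filled <- if (method == "chained") {
        impute_variable_pmm(wide, n_iter = n_iter, donors = donors)
      } else {
        impute_variable_norm(wide, lo = params[1], hi = params[2])
      }
      done[done$timepoint == tp[2], v] <- filled$y1
      done[done$timepoint == tp[3], v] <- filled$y2
    }
    panels[[j]] <- done
  }
  structure(list(m = as.integer(m), method = method, seed = as.integer(seed),
                 panels = panels, source = panel),
            class = "imputation_set")
}

instrument_range <- function(v, panel) {
  defaults <- default_outcome_params()
  if (v %in% rownames(defaults))
    c(defaults[v, "range_min"], defaults[v, "range_max"])
  else range(panel[[v]], na.rm = TRUE)
}

panel_to_wide <- function(panel, v, tp) {
  d <- as.data.frame(panel)
  base <- d[d$timepoint == tp[1], ]
  list(arm = as.integer(base$arm == "intervention"),
       endo = base$endocrine_therapy,
       y0 = base[[v]],
       y1 = d[d$timepoint == tp[2], v],
       y2 = d[d$timepoint == tp[3], v])
}

# draw (beta, sigma) from the approximate posterior of a Gaussian lm
bayes_lm_draw <- function(X, y) {
  qx <- qr(X)
  beta_hat <- qr.coef(qx, y)
  res <- y - X %*% beta_hat
  df <- max(1, length(y) - ncol(X))
  sigma2 <- sum(res^2) / stats::rchisq(1, df)
  Rinv <- backsolve(qr.R(qx), diag(ncol(X)))
  beta <- beta_hat + sqrt(sigma2) * (Rinv %*% stats::rnorm(ncol(X)))
  list(beta = as.vector(beta), sigma = sqrt(sigma2))
}

pmm_draw <- function(pred_obs, y_obs, pred_mis, donors) {
  vapply(pred_mis, function(p) {
    d <- abs(pred_obs - p)
    pool <- order(d)[seq_len(min(donors, length(d)))]
    y_obs[sample(pool, 1)]
  }, numeric(1))
}

impute_variable_pmm <- function(w, n_iter, donors) {
  mis1 <- is.na(w$y1); mis2 <- is.na(w$y2)
  y1 <- w$y1; y2 <- w$y2
  obs_pool <- c(y1[!mis1], y2[!mis2])
  if (any(mis1)) y1[mis1] <- sample(obs_pool, sum(mis1), replace = TRUE)
  if (any(mis2)) y2[mis2] <- sample(obs_pool, sum(mis2), replace = TRUE)
  for (it in seq_len(n_iter)) {
    if (any(mis1)) {
      X <- cbind(1, w$arm, w$endo, w$y0, y2)
      dr <- bayes_lm_draw(X[!mis1, , drop = FALSE], y1[!mis1])
      pred <- as.vector(X %*% dr$beta)
      y1[mis1] <- pmm_draw(pred[!mis1], y1[!mis1], pred[mis1], donors)
    }
    if (any(mis2)) {
      X <- cbind(1, w$arm, w$endo, w$y0, y1)
      dr <- bayes_lm_draw(X[!mis2, , drop = FALSE], y2[!mis2])
      pred <- as.vector(X %*% dr$beta)
      y2[mis2] <- pmm_draw(pred[!mis2], y2[!mis2], pred[mis2], donors)
    }
  }
  list(y1 = y1, y2 = y2)
}

impute_variable_norm <- function(w, lo, hi) {
  mis1 <- is.na(w$y1); mis2 <- is.na(w$y2)
  y1 <- w$y1; y2 <- w$y2
  cc <- !mis1 & !mis2
  # monotone factorization: y1 | baseline, then y2 | baseline, y1
  X1 <- cbind(1, w$arm, w$endo, w$y0)
  d1 <- bayes_lm_draw(X1[!mis1, , drop = FALSE], y1[!mis1])
  if (any(mis1))
    y1[mis1] <- as.vector(X1[mis1, , drop = FALSE] %*% d1$beta) +
      stats::rnorm(sum(mis1), 0, d1$sigma)
  X2 <- cbind(1, w$arm, w$endo, w$y0, y1)
  d2 <- bayes_lm_draw(X2[cc, , drop = FALSE], y2[cc])
  if (any(mis2))
    y2[mis2] <- as.vector(X2[mis2, , drop = FALSE] %*% d2$beta) +
      stats::rnorm(sum(mis2), 0, d2$sigma)
  list(y1 = pmin(pmax(y1, lo), hi), y2 = pmin(pmax(y2, lo), hi))
}

#' @export
print.imputation_set <- function(x, ...) {
  cat(sprintf("<imputation_set> m = %d (%s), seed %d\n",
              x$m, x$method, x$seed))
  invisible(x)
}

#' Pool estimates across imputations by Rubin's rules
#'
#' Combines per-imputation point estimates and variances: the pooled point
#' is the mean, the total variance is the within-imputation variance plus
#' `(1 + 1/m)` times the between-imputation variance, and the
#' small-sample degrees of freedom are
#' `(m - 1) * (1 + within / ((1 + 1/m) * between))^2` (infinite when the
#' between-imputation variance is zero or `m = 1`).
#'
#' @param points numeric vector of per-imputation estimates.
#' @param variances numeric vector of per-imputation variances.
#' @return A `pooled_estimate`: list with `point`, `within_var`,
#'   `between_var`, `total_var`, `se`, `df`, `m`.
#' @examples
#' pool_rubin(c(0, 2), c(1, 1))$total_var  # 1 + (1 + 1/2) * 2 = 4
#' @export
pool_rubin <- function(points, variances) {
  m <- length(points)
  if (m == 0) stop("no estimates to pool", call. = FALSE)
  if (length(variances) != m || any(variances <= 0))
    stop("need one positive variance per estimate", call. = FALSE)
  point <- mean(points)
  within <- mean(variances)
  between <- if (m > 1) stats::var(points) else 0
  total <- within + (1 + 1 / m) * between
  df <- if (between > 0 && m > 1)
    (m - 1) * (1 + within / ((1 + 1 / m) * between))^2 else Inf
  structure(list(point = point, within_var = within, between_var = between,
                 total_var = total, se = sqrt(total), df = df, m = m),
            class = "pooled_estimate")
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf("<pooled_estimate> %.4g (SE %.4g, df %.1f, m = %d)\n",
              x$point, x$se, x$df, x$m))
  invisible(x)
}
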