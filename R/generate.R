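#' Generate a complete synthetic two-arm trial panel
#'
#' Draws a long-format participant x timepoint panel with the statistical
#' structure the downstream analysis assumes. For each instrument, a
#' participant's scores across the three assessments are multivariate
#' normal with an exchangeable correlation `within_subject_rho`; the
#' control arm follows the configured drift and the intervention arm
#' additionally receives the configured additive effect at T1/T2. Scores
#' are then truncated to the instrument range and, for integer scale
#' totals, rounded. Cumulative 6-month direct medical costs are lognormal
#' per arm; inpatient days and clinic visits are Poisson; app usage
#' (intervention arm only) is a correlated lognormal total split across
#' the three program modules. The returned panel is complete: apply
#' [apply_missingness()] to introduce follow-up dropout.
#'
#' Truncation happens after effect addition, so configurations that push
#' means near a range boundary bias the realized marginal means; the
#' default parameters keep truncation negligible for every instrument
#' except the floor of the BIS, which both arms share.
#'
#' @param config a [trial_config()].
#' @return An `outcome_panel`: a data frame with one row per participant
#'   per timepoint. Participant-level fields (arm, endocrine therapy,
#'   costs, usage) are repeated on each of the participant's rows.
#' @examples
#' panel <- generate_trial(trial_config(n_per_arm = 10, seed = 7))
#' nrow(panel)  # 2 * 10 * 3
#' @export
generate_trial <- function(config) {
  validate_trial_config(config)
  set.seed(child_seed(config$seed, "generate"))
  n <- config$n_per_arm
  n_tot <- 2L * n
  tp <- config$timepoints
  n_t <- length(tp)
  arms <- rep(c("intervention", "control"), each = n)
  id <- sprintf("P%03d", seq_len(n_tot))

  endo <- c(stats::rbinom(n, 1, config$endocrine_prevalence[["intervention"]]),
            stats::rbinom(n, 1, config$endocrine_prevalence[["control"]]))

  rho <- config$within_subject_rho
  R <- matrix(rho, n_t, n_t); diag(R) <- 1

  scores <- list()
  for (k in seq_len(nrow(config$outcome_params))) {
    p <- config$outcome_params[k, ]
    mu <- matrix(p$baseline_mean, n_tot, n_t)
    drift <- c(0, p$drift_t1, p$drift_t2)[seq_len(n_t)]
    eff <- c(0, p$effect_t1, p$effect_t2)[seq_len(n_t)]
    mu <- mu + matrix(drift, n_tot, n_t, byrow = TRUE)
    mu[arms == "intervention", ] <- mu[arms == "intervention", ] +
      matrix(eff, sum(arms == "intervention"), n_t, byrow = TRUE)
    draw <- MASS::mvrnorm(n_tot, rep(0, n_t), p$baseline_sd^2 * R)
    x <- mu + draw
    x <- pmin(pmax(x, p$range_min), p$range_max)
    if (p$integer) x <- round(x)
    scores[[p$instrument]] <- x
  }

  cp <- config$cost_params
  direct <- numeric(n_tot)
  inpat <- integer(n_tot)
  visits <- integer(n_tot)
  for (a in c("intervention", "control")) {
    sel <- arms == a
    lp <- lnorm_params(cp$direct_mean[[a]], cp$direct_sd[[a]])
    direct[sel] <- stats::rlnorm(sum(sel), lp$meanlog, lp$sdlog)
    inpat[sel] <- stats::rpois(sum(sel), cp$inpatient_mean[[a]])
    visits[sel] <- stats::rpois(sum(sel), cp$clinic_visit_mean[[a]])
  }

  usage <- generate_usage(sum(arms == "intervention"), config$usage_params)
  usage_full <- as.data.frame(
    lapply(usage, function(col) c(col, rep(NA_real_, n))))

  base <- data.frame(participant_id = id, arm = arms,
                     endocrine_therapy = endo,
                     direct_cost = direct, inpatient_days = inpat,
                     clinic_visits = visits, stringsAsFactors = FALSE)
  base <- cbind(base, usage_full)

  panel <- base[rep(seq_len(n_tot), each = n_t), , drop = FALSE]
  panel$timepoint <- rep(tp, times = n_tot)
  panel$time_years <- rep(config$times_years, times = n_tot)
  for (nm in names(scores)) panel[[nm]] <- as.vector(t(scores[[nm]]))
  rownames(panel) <- NULL

  cols <- c("participant_id", "arm", "endocrine_therapy", "timepoint",
            "time_years", names(scores), "direct_cost", "inpatient_days",
            "clinic_visits", names(usage))
  panel <- panel[, cols]
  class(panel) <- c("outcome_panel", "data.frame")
  panel
}

# mean/sd on the natural scale -> lognormal meanlog/sdlog
lnorm_params <- function(m, s) {
  if (m <= 0) stop("lognormal mean must be > 0", call. = FALSE)
  sdlog2 <- log(1 + (s / m)^2)
  list(meanlog = log(m) - sdlog2 / 2, sdlog = sqrt(sdlog2))
}

generate_usage <- function(n, up) {
  S <- matrix(c(up$duration_sdlog^2,
                up$log_correlation * up$duration_sdlog * up$logins_sdlog,
                up$log_correlation * up$duration_sdlog * up$logins_sdlog,
                up$logins_sdlog^2), 2, 2)
  z <- MASS::mvrnorm(n, c(up$duration_meanlog, up$logins_meanlog), S)
  minutes <- exp(z[, 1])
  logins <- pmax(1, round(exp(z[, 2])))
  mods <- names(up$module_share_duration)
  a0 <- up$share_concentration
  sh_d <- matrix(stats::rgamma(n * 3, shape = rep(a0 * up$module_share_duration,
                                                  each = n)), n, 3)
  sh_d <- sh_d / rowSums(sh_d)
  out <- list(usage_minutes_total = minutes, usage_logins_total = logins)
  login_split <- t(vapply(seq_len(n), function(i)
    as.vector(stats::rmultinom(1, logins[i], up$module_share_logins)),
    numeric(3)))
  for (j in seq_along(mods)) {
    out[[paste0("usage_minutes_", mods[j])]] <- minutes * sh_d[, j]
    out[[paste0("usage_logins_", mods[j])]] <- login_split[, j]
  }
  out
}

#' Instrument columns of a panel
#'
#' @param panel an `outcome_panel`.
#' @return Character vector of score/utility column names present.
#' @export
panel_instruments <- function(panel) {
  intersect(c("bis", "sis", "psqi", "mspss", "pcs", "mcs", "utility"),
            names(panel))
}

#' Impose monotone follow-up dropout on a complete panel
#'
#' Masks the analysis variables (instrument scores and utility) at dropped
#' timepoints; baseline rows are never masked, matching a design where all
#' analyzed participants completed the baseline assessment. Dropout is
#' monotone: a participant either misses T1 and T2 or misses T2 only.
#' Under `MAR` the per-participant dropout probability is a logistic
#' function of the standardized baseline stigma (SIS) score and arm,
#' with the intercept solved so the expected overall dropout equals
#' `rate`; under `MCAR` every participant has probability `rate`.
#' Costs and usage are participant-level records and stay complete.
#'
#' @param panel a complete `outcome_panel`.
#' @param rate target fraction of participants with any missing follow-up,
#'   in `[0, 1)`.
#' @param mechanism `"MAR"` or `"MCAR"`.
#' @param seed integer seed.
#' @param beta_baseline,beta_arm MAR log-odds coefficients (standardized
#'   baseline SIS; intervention-arm indicator).
#' @param t1_share fraction of dropouts missing from T1 onward.
#' @param driver instrument whose baseline value drives MAR dropout.
#' @return The panel with `NA` analysis values at dropped timepoints.
#' @export
apply_missingness <- function(panel, rate, mechanism = c("MAR", "MCAR"),
                              seed = 1L, beta_baseline = 0.6,
                              beta_arm = 0.2, t1_share = 0.5,
                              driver = "sis") {
  mechanism <- match.arg(mechanism)
  if (!is.numeric(rate) || rate < 0 || rate >= 1)
    stop("dropout `rate` must lie in [0, 1)", call. = FALSE)
  if (rate == 0) return(panel)
  tp <- unique(panel$timepoint)
  base <- panel[panel$timepoint == tp[1], ]
  if (anyNA(base[panel_instruments(panel)]))
    stop("baseline rows must be complete before applying missingness",
         call. = FALSE)
  set.seed(seed)
  n <- nrow(base)
  if (mechanism == "MCAR") {
    p <- rep(rate, n)
  } else {
    z <- as.numeric(scale(base[[driver]]))
    lin <- beta_baseline * z + beta_arm * (base$arm == "intervention")
    # solve the intercept so the mean dropout probability hits `rate`
    a <- stats::uniroot(function(a) mean(stats::plogis(a + lin)) - rate,
                        c(-30, 30))$root
    p <- stats::plogis(a + lin)
  }
  drops <- stats::runif(n) < p
  from_t1 <- drops & (stats::runif(n) < t1_share)
  vars <- panel_instruments(panel)
  follow <- tp[-1]
  for (i in which(drops)) {
    miss_tp <- if (from_t1[i]) follow else follow[length(follow)]
    sel <- panel$participant_id == base$participant_id[i] &
      panel$timepoint %in% miss_tp
    panel[sel, vars] <- NA
  }
  panel
}

#' Write / read an outcome panel as comma-separated text
#'
#' `read_panel()` validates the schema strictly: the required identifier,
#' design and analysis columns must be present with the right types, with
#' an error naming what is missing.
#'
#' @param panel an `outcome_panel`.
#' @param path file path.
#' @return `read_panel()` returns an `outcome_panel`.
#' @export
write_panel <- function(panel, path) {
  utils::write.csv(as.data.frame(panel), path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_panel
#' @export
read_panel <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE,
                       na.strings = c("NA", ""))
  required <- c("participant_id", "arm", "timepoint", "time_years",
                "endocrine_therapy", "direct_cost", "inpatient_days",
                "clinic_visits")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols))
    stop("panel file lacks required columns: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  if (!all(x$arm %in% c("intervention", "control")))
    stop("column `arm` must be 'intervention' or 'control'", call. = FALSE)
  if (!is.numeric(x$time_years))
    stop("column `time_years` must be numeric", call. = FALSE)
  if (length(panel_instruments(x)) == 0)
    stop("panel file contains no instrument columns", call. = FALSE)
  counts <- table(x$participant_id)
  if (length(unique(counts)) != 1)
    stop("panel must have one row per participant per timepoint",
         call. = FALSE)
  class(x) <- c("outcome_panel", "data.frame")
  x
}

#' @export
print.outcome_panel <- function(x, ...) {
  n_id <- length(unique(x$participant_id))
  cat(sprintf("<outcome_panel> %d participants x %d timepoints (%d rows)\n",
              n_id, length(unique(x$timepoint)), nrow(x)))
  cat(sprintf("  instruments: %s\n",
              paste(panel_instruments(x), collapse = ", ")))
  miss <- sum(is.na(as.data.frame(x)[panel_instruments(x)]))
  cat(sprintf("  missing analysis cells: %d\n", miss))
  invisible(x)
}

#' One row per participant (design, costs and usage)
#'
#' @param panel an `outcome_panel`.
#' @return Data frame with one row per participant holding the
#'   participant-level fields.
#' @export
participant_table <- function(panel) {
  tp <- unique(panel$timepoint)[1]
  out <- as.data.frame(panel)[panel$timepoint == tp, ]
  keep <- setdiff(names(out), c("timepoint", "time_years",
                                panel_instruments(panel)))
  rownames(out) <- NULL
  out[, keep]
}
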