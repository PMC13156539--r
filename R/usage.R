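#' Summarize app-usage records
#'
#' Per-module and whole-program summaries (median, IQR, mean, SD, max) of
#' 3-month usage duration in minutes and login frequency, plus the
#' expected-use rate: the fraction of intervention-arm participants with
#' at least `min_logins` total logins AND `min_minutes` total minutes
#' (thresholds inclusive).
#'
#' @param x an `outcome_panel` (usage columns are read from the
#'   intervention arm) or a participant-level data frame with
#'   `usage_minutes_*` / `usage_logins_*` columns.
#' @param min_logins,min_minutes expected-use thresholds.
#' @return List with `summary` (one row per module and for the whole
#'   program), `expected_use` (per-participant logical flags) and
#'   `expected_use_rate`.
#' @examples
#' panel <- generate_trial(trial_config(n_per_arm = 30, seed = 2))
#' summarize_usage(panel)$expected_use_rate
#' @export
summarize_usage <- function(x, min_logins = 10, min_minutes = 50) {
  d <- if (inherits(x, "outcome_panel") || "timepoint" %in% names(x))
    participant_table(x) else x
  d <- d[!is.na(d$usage_minutes_total), , drop = FALSE]
  if (nrow(d) == 0) stop("no usage records", call. = FALSE)
  mods <- sub("^usage_minutes_", "",
              grep("^usage_minutes_", names(d), value = TRUE))
  mods <- c(setdiff(mods, "total"), "total")
  stat_row <- function(v) {
    qs <- stats::quantile(v, c(0.5, 0.25, 0.75), names = FALSE)
    c(median = qs[1], q1 = qs[2], q3 = qs[3], mean = mean(v),
      sd = stats::sd(v), max = max(v))
  }
  rows <- lapply(mods, function(m) {
    mins <- stat_row(d[[paste0("usage_minutes_", m)]])
    logs <- stat_row(d[[paste0("usage_logins_", m)]])
    data.frame(module = m,
               t(stats::setNames(mins, paste0("minutes_", names(mins)))),
               t(stats::setNames(logs, paste0("logins_", names(logs)))),
               stringsAsFactors = FALSE)
  })
  flags <- d$usage_logins_total >= min_logins &
    d$usage_minutes_total >= min_minutes
  list(summary = do.call(rbind, rows),
       expected_use = stats::setNames(flags, d$participant_id),
       expected_use_rate = mean(flags))
}
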