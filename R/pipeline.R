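# single-observation-per-participant adjusted contrast (HC0 sandwich);
# reuses the estimating-equation solver with one-row clusters
adjusted_arm_contrast <- function(y, d, extra = NULL) {
  X <- cbind(intercept = 1, group = as.numeric(d$arm == "intervention"),
             endocrine = d$endocrine_therapy)
  if (!is.null(extra)) X <- cbind(X, extra = extra)
  f <- gee_exchangeable(y, X, id = seq_along(y), corstr = "independence")
  means <- vapply(c(intervention = 1, control = 0), function(g) {
    xv <- c(1, g, mean(d$endocrine_therapy),
            if (!is.null(extra)) mean(extra))
    c(sum(xv * f$beta), sqrt(as.numeric(t(xv) %*% f$vcov_robust %*% xv)))
  }, numeric(2))
  list(diff = unname(f$beta["group"]),
       var = f$vcov_robust["group", "group"],
       mean_i = means[1, "intervention"], se_i = means[2, "intervention"],
       mean_c = means[1, "control"], se_c = means[2, "control"])
}

pool_contrast_rows <- function(per_imp, label) {
  diffs <- vapply(per_imp, `[[`, numeric(1), "diff")
  vars <- vapply(per_imp, `[[`, numeric(1), "var")
  pooled <- pool_rubin(diffs, vars)
  q <- if (is.finite(pooled$df)) stats::qt(0.975, pooled$df)
       else stats::qnorm(0.975)
  stat <- pooled$point / pooled$se
  p <- if (is.finite(pooled$df)) 2 * stats::pt(-abs(stat), pooled$df)
       else 2 * stats::pnorm(-abs(stat))
  data.frame(
    item = label,
    mean_intervention = mean(vapply(per_imp, `[[`, numeric(1), "mean_i")),
    se_intervention = mean(vapply(per_imp, `[[`, numeric(1), "se_i")),
    mean_control = mean(vapply(per_imp, `[[`, numeric(1), "mean_c")),
    se_control = mean(vapply(per_imp, `[[`, numeric(1), "se_c")),
    difference = pooled$point,
    ci_low = pooled$point - q * pooled$se,
    ci_high = pooled$point + q * pooled$se,
    p_value = p, stringsAsFactors = FALSE)
}

#' Cost, utility and QALY table
#'
#' Builds the economic-outcomes analogue of the trial's cost table: the
#' per-participant fixed-cost share, adjusted direct, indirect and total
#' 6-month societal costs per arm (adjusted for endocrine therapy, robust
#' SEs), adjusted SF-6D-style utilities at each assessment, and
#' covariate-adjusted QALYs accrued to T1 and T2 (adjusted for endocrine
#' therapy and baseline utility), pooled over imputations.
#'
#' @param x a completed `outcome_panel` or `imputation_set`.
#' @param cost_params list as in [default_cost_params()].
#' @return Data frame, one row per economic quantity.
#' @export
economics_table <- function(x, cost_params = default_cost_params()) {
  panels <- if (inherits(x, "imputation_set")) x$panels else list(x)
  cb <- lapply(panels, cost_breakdown, cost_params = cost_params)
  rows <- list()
  for (comp in c("direct", "indirect", "total")) {
    per <- lapply(cb, function(d) adjusted_arm_contrast(d[[comp]], d))
    rows[[comp]] <- pool_contrast_rows(per, paste0("cost_", comp))
  }
  share <- cb[[1]]$fixed_share[cb[[1]]$arm == "intervention"][1]
  fixed_row <- data.frame(item = "cost_fixed", mean_intervention = share,
                          se_intervention = NA, mean_control = 0,
                          se_control = NA, difference = NA, ci_low = NA,
                          ci_high = NA, p_value = NA)
  tp <- unique(panels[[1]]$timepoint)
  urows <- list()
  for (t in tp) {
    per <- lapply(panels, function(p) {
      d <- as.data.frame(p)[p$timepoint == t, ]
      adjusted_arm_contrast(d$utility, d)
    })
    urows[[t]] <- pool_contrast_rows(per, paste0("utility_", t))
  }
  qrows <- list()
  for (t in tp[-1]) {
    per <- lapply(panels, function(p) {
      q <- participant_qalys(p, upto = t)
      adjusted_arm_contrast(q$qaly, q, extra = q$baseline_utility)
    })
    qrows[[t]] <- pool_contrast_rows(per, paste0("qaly_to_", t))
  }
  out <- rbind(fixed_row, do.call(rbind, rows), do.call(rbind, urows),
               do.call(rbind, qrows))
  rownames(out) <- NULL
  out
}

#' Baseline characteristics table
#'
#' Per-arm baseline means (SD) of every instrument plus the endocrine
#' therapy prevalence.
#'
#' @param panel an `outcome_panel`.
#' @return Data frame, one row per characteristic.
#' @export
baseline_table <- function(panel) {
  tp <- unique(panel$timepoint)[1]
  d <- as.data.frame(panel)[panel$timepoint == tp, ]
  rows <- lapply(panel_instruments(panel), function(v) {
    s <- split(d[[v]], d$arm)
    data.frame(variable = v,
               mean_intervention = mean(s$intervention),
               sd_intervention = stats::sd(s$intervention),
               mean_control = mean(s$control),
               sd_control = stats::sd(s$control), stringsAsFactors = FALSE)
  })
  endo <- split(d$endocrine_therapy, d$arm)
  rows[[length(rows) + 1]] <- data.frame(
    variable = "endocrine_therapy",
    mean_intervention = mean(endo$intervention), sd_intervention = NA,
    mean_control = mean(endo$control), sd_control = NA)
  do.call(rbind, rows)
}

#' Run the whole synthetic-trial analysis pipeline
#'
#' Executes generate -> missingness -> impute -> effectiveness -> costs /
#' QALYs -> bootstrap CEA -> usage summary, and assembles the five
#' analysis tables (baseline, effectiveness contrasts, the MCMC-imputation
#' sensitivity analysis of the primary outcomes, economic outcomes, usage)
#' plus three figures (outcome trajectories, cost-effectiveness plane,
#' CEAC) and a run manifest. Identical configurations reproduce identical
#' tables byte for byte.
#'
#' @param config a [trial_config()].
#' @param out_dir optional directory; when given, tables are written as
#'   comma-separated text, figures as PNG, and the manifest (with file
#'   checksums) as YAML.
#' @param quiet suppress stage progress messages.
#' @return Invisibly, a list with `tables` (named list of 5 data frames),
#'   `figures` (named list of 3 ggplot objects), `cea` (the
#'   [cea_evaluate()] result), `panel`, `imputations` and `manifest`.
#' @export
run_pipeline <- function(config = trial_config(), out_dir = NULL,
                         quiet = FALSE) {
  validate_trial_config(config)
  say <- function(...) if (!quiet) message(sprintf(...))
  stage <- "generate"
  result <- tryCatch({
    say("[generate] 2 x %d participants (seed %d)", config$n_per_arm,
        config$seed)
    panel0 <- generate_trial(config)

    stage <- "missingness"
    panel <- if (config$dropout_rate > 0) {
      say("[missingness] MAR dropout, target rate %.3f", config$dropout_rate)
      apply_missingness(panel0, config$dropout_rate, "MAR",
                        seed = child_seed(config$seed, "missingness"),
                        beta_baseline = config$mar_beta_baseline,
                        beta_arm = config$mar_beta_arm,
                        t1_share = config$dropout_t1_share)
    } else panel0

    stage <- "impute"
    say("[impute] chained equations, m = %d", config$m)
    imps <- impute_panel(panel, m = config$m, method = "chained",
                         seed = child_seed(config$seed, "impute"))
    imps_mcmc <- impute_panel(panel, m = config$m, method = "mcmc",
                              seed = child_seed(config$seed, "impute-mcmc"))

    stage <- "effects"
    say("[effects] GEE contrasts for 6 instruments")
    table2 <- effects_table(imps)
    table3 <- effects_table(imps_mcmc, outcomes = c("bis", "sis"))

    stage <- "costs"
    say("[costs] societal cost model + QALYs")
    table4 <- economics_table(imps, config$cost_params)

    stage <- "cea"
    say("[cea] stratified bootstrap, B = %d", config$n_bootstrap)
    cea_in <- participant_cea_data(imps, config$cost_params)
    cea_res <- cea_evaluate(cea_in, B = config$n_bootstrap,
                            seed = child_seed(config$seed, "bootstrap"),
                            lambda_grid = config$wtp_grid,
                            threshold = config$wtp_threshold)

    stage <- "usage"
    usage <- summarize_usage(panel0,
                             min_logins = config$usage_params$min_logins,
                             min_minutes = config$usage_params$min_minutes)
    table5 <- usage$summary
    table5$expected_use_rate <- usage$expected_use_rate

    stage <- "report"
    figures <- list(
      outcome_trajectories = plot_outcome_trajectories(panel0),
      ce_plane = plot_ce_plane(cea_res),
      ceac = plot_ceac(cea_res))
    tables <- list(baseline = baseline_table(panel0),
                   effects = table2, sensitivity = table3,
                   economics = table4, usage = table5)
    list(tables = tables, figures = figures, cea = cea_res,
         panel = panel, imputations = imps)
  }, error = function(e) {
    stop(sprintf("pipeline stage `%s` failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  })

  manifest <- list(
    package_version = as.character(utils::packageVersion("trialcea")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    seed = config$seed,
    stage_seeds = list(
      generate = child_seed(config$seed, "generate"),
      missingness = child_seed(config$seed, "missingness"),
      impute = child_seed(config$seed, "impute"),
      impute_mcmc = child_seed(config$seed, "impute-mcmc"),
      bootstrap = child_seed(config$seed, "bootstrap")),
    n_per_arm = config$n_per_arm, m = config$m, B = config$n_bootstrap)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    paths <- character(0)
    for (nm in names(result$tables)) {
      p <- file.path(out_dir, paste0("table_", nm, ".csv"))
      utils::write.csv(render_table(result$tables[[nm]]), p,
                       row.names = FALSE, na = "")
      paths <- c(paths, p)
    }
    p <- file.path(out_dir, "ceac.csv")
    utils::write.csv(render_table(result$cea$ceac), p, row.names = FALSE)
    paths <- c(paths, p)
    p <- file.path(out_dir, "cea_draws.csv")
    utils::write.csv(render_table(as.data.frame(result$cea$draws)), p,
                     row.names = FALSE)
    paths <- c(paths, p)
    for (nm in names(result$figures)) {
      fp <- file.path(out_dir, paste0("figure_", nm, ".png"))
      ggplot2::ggsave(fp, result$figures[[nm]], width = 7, height = 5,
                      dpi = 150)
    }
    manifest$checksums <- as.list(tools::md5sum(paths))
    names(manifest$checksums) <- basename(paths)
    write_trial_config(config, file.path(out_dir, "config.yaml"))
    yaml::write_yaml(manifest, file.path(out_dir, "manifest.yaml"))
  }
  result$manifest <- manifest
  invisible(result)
}

# display rounding: half-up to 2 decimals, applied only at render time
round_half_up <- function(x, digits = 2) {
  s <- 10^digits
  sign(x) * floor(abs(x) * s + 0.5) / s
}

render_table <- function(df) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v)
    ifelse(abs(v) < 1, signif(v, 4), round_half_up(v, 2)))
  df
}
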