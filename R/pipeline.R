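# End-to-end driver: simulate (or read) monitoring and rainfall series,
# impute, detect breakpoints, test annual periodicity per regime, cluster
# the final-regime monthly profiles, and scan cumulative-rainfall lags on
# the weekly panel. Writes a delimited-text report bundle that is
# byte-identical for identical (config, seed).

#' Default per-marker simulation configurations
#'
#' A four-marker emulation of a 32-year urban drinking-water survey:
#' shared rainfall and shared regime-shift dates, with marker-specific
#' baseline levels, a month-of-year effect for TC, IE and (weakly) SSRC but
#' none for EC, and marker-specific cumulative-rainfall lags on the weekly
#' panel (8, 5 and 4 weeks for TC, IE and SSRC; no rainfall effect for EC).
#'
#' @param resolution `"monthly"` or `"weekly"`.
#' @param years series length in years (32 monthly / 6 weekly by default).
#' @param seed integer seed.
#' @param start_year first calendar year.
#' @return Named list of [sim_config()] for TC, EC, IE, SSRC.
#' @export
default_marker_configs <- function(resolution = c("monthly", "weekly"),
                                   years = NULL, seed = 1L,
                                   start_year = NULL) {
  resolution <- match.arg(resolution)
  if (resolution == "monthly") {
    if (is.null(years)) years <- 32L
    if (is.null(start_year)) start_year <- 1986L
    mk <- function(levels, month_amp, beta) {
      # the 4-regime staircase needs the long default break pattern; short
      # panels fall back to a flat baseline at the first level
      if (years < 28) levels <- levels[1L]
      sim_config(years = years, resolution = "monthly", seed = seed,
                 start_year = start_year,
                 baseline_logit = stats::qlogis(levels),
                 break_times = if (years < 28) integer(0) else NULL,
                 month_effect_amplitude = month_amp,
                 lag_true = 1L, effect_beta = beta)
    }
    list(TC = mk(c(0.020, 0.005, 0.010, 0.030), 0.6, 0.002),
         EC = mk(c(0.003, 0.001, 0.002, 0.007), 0.0, 0.000),
         IE = mk(c(0.004, 0.002, 0.004, 0.012), 0.6, 0.002),
         SSRC = mk(c(0.020, 0.004, 0.020, 0.050), 0.25, 0.002))
  } else {
    if (is.null(years)) years <- 6L
    if (is.null(start_year)) start_year <- 2012L
    mk <- function(level, month_amp, beta, lag) {
      sim_config(years = years, resolution = "weekly", seed = seed,
                 start_year = start_year,
                 baseline_logit = stats::qlogis(level), break_times = integer(0),
                 month_effect_amplitude = month_amp,
                 lag_true = lag, effect_beta = beta)
    }
    list(TC = mk(0.030, 0.3, 0.004, 8L),
         EC = mk(0.006, 0.0, 0.000, 4L),
         IE = mk(0.015, 0.3, 0.005, 5L),
         SSRC = mk(0.040, 0.2, 0.006, 4L))
  }
}

#' Pipeline configuration
#'
#' Collects the knobs of [run_pipeline()]: the simulated panels (a long
#' monthly panel for breakpoints/periodicity/clustering and a short weekly
#' panel for the lag scan), or paths to monitoring/rainfall files in the
#' package's delimited format, plus per-stage parameters.
#'
#' @param seed master seed; every stochastic stage derives its seed from it.
#' @param years_monthly,years_weekly simulated panel lengths (years);
#'   `years_weekly = NULL` skips the weekly panel and the lag scan.
#' @param monthly_inputs,weekly_inputs optional `list(monitoring =,
#'   rainfall =)` file paths that replace simulation for that panel.
#' @param m_max,h breakpoint-stage settings (`NULL` = defaults).
#' @param ci_bootstrap bootstrap replicates for break-date intervals.
#' @param n_permutations periodicity-stage permutations.
#' @param k number of clusters.
#' @param lag_grid,validation_years lag-scan settings.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, years_monthly = 32L,
                            years_weekly = 6L,
                            monthly_inputs = NULL, weekly_inputs = NULL,
                            m_max = NULL, h = NULL, ci_bootstrap = 199L,
                            n_permutations = 999L, k = 4L,
                            lag_grid = 1:10, validation_years = 2L) {
  cfg <- list(seed = as.integer(seed), years_monthly = years_monthly,
              years_weekly = years_weekly,
              monthly_inputs = monthly_inputs, weekly_inputs = weekly_inputs,
              m_max = m_max, h = h, ci_bootstrap = as.integer(ci_bootstrap),
              n_permutations = as.integer(n_permutations), k = as.integer(k),
              lag_grid = lag_grid, validation_years = validation_years)
  class(cfg) <- "pipeline_config"
  cfg
}

load_panel <- function(inputs, resolution, years, seed, lag_grid) {
  if (!is.null(inputs)) {
    list(series = read_monitoring(inputs$monitoring, resolution),
         rain = read_rainfall(inputs$rainfall, resolution))
  } else {
    cfgs <- default_marker_configs(resolution, years = years, seed = seed)
    warm <- max(vapply(cfgs, `[[`, integer(1), "lag_true"),
                if (resolution == "weekly") max(lag_grid) else 0L)
    rain <- gen_rainfall(cfgs[[1L]], warmup = warm)
    series <- gen_monitoring(rain, cfgs)
    series <- Map(function(s, i) {
      inject_missing(s, cfgs[[1L]]$missing_rate, seed = seed + 17L * i,
                     ensure_donor = TRUE)
    }, series, seq_along(series))
    list(series = series, rain = rain)
  }
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) the monitoring panels, imputes missing periods by
#' the period-of-year median, then runs breakpoint detection with
#' BIC-selected break counts and bootstrap intervals, per-regime annual
#' periodicity permutation tests, Ward clustering of the final-regime
#' monthly profiles, and the cumulative-rainfall lag scan on the weekly
#' panel. All reports are written as CSV under `output_dir` together with a
#' run manifest; a rerun with the same configuration is byte-identical.
#'
#' @param config a [pipeline_config()].
#' @param output_dir directory for the report bundle (created if needed).
#' @return Invisibly, a list with the in-memory stage results.
#' @export
run_pipeline <- function(config = pipeline_config(), output_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  wpath <- function(f) file.path(output_dir, f)
  note <- function(...) message("[watermon] ", ...)

  note("stage simulate/load: monthly panel")
  monthly <- load_panel(config$monthly_inputs, "monthly",
                        config$years_monthly, config$seed, config$lag_grid)
  mseries <- monthly$series
  validate_total(mseries)
  write_monitoring(mseries, wpath("monitoring_monthly.csv"))
  write_rainfall(monthly$rain, wpath("rainfall_monthly.csv"))

  note("stage impute")
  imputed <- lapply(mseries, impute_median_by_period)
  # restrict rainfall to the monitoring index for the analysis stages
  ridx <- match(paste(imputed[[1L]]$year, imputed[[1L]]$period),
                paste(monthly$rain$year, monthly$rain$period))
  rain_m <- rainfall_series(monthly$rain$year[ridx],
                            monthly$rain$period[ridx],
                            monthly$rain$rain_mm[ridx], "monthly")

  note("stage breakpoints")
  bp_inputs <- c(imputed, list(Rainfall = rain_m))
  fits <- lapply(bp_inputs, function(s) {
    f <- select_num_breaks(s, m_max = config$m_max, h = config$h)
    if (f$selected_m > 0L) {
      f <- break_confidence_intervals(f, B = config$ci_bootstrap,
                                      seed = config$seed + 101L)
    }
    f
  })
  index <- data.frame(year = imputed[[1L]]$year,
                      period = imputed[[1L]]$period)
  bp_tab <- breakpoint_report(fits, index)
  utils::write.csv(bp_tab, wpath("breakpoints.csv"), row.names = FALSE,
                   na = "")

  note("stage periodicity")
  total_fit <- fits[["TOTAL"]]
  seg_bounds <- c(0L, total_fit$breaks, total_fit$n)
  blocks <- lapply(seq_len(length(seg_bounds) - 1L), function(s) {
    rows <- (seg_bounds[s] + 1L):seg_bounds[s + 1L]
    c(index$year[rows[1L]], index$year[rows[length(rows)]])
  })
  names(blocks) <- vapply(blocks, function(b) paste(b, collapse = "-"),
                          character(1))
  per_tab <- batch_month_effect(c(imputed, list(Rainfall = rain_m)), blocks,
                                n_permutations = config$n_permutations,
                                seed = config$seed + 202L)
  utils::write.csv(per_tab, wpath("periodicity_pvalues.csv"),
                   row.names = FALSE, na = "")

  note("stage clustering (final regime)")
  final_from <- index$year[seg_bounds[length(seg_bounds) - 1L] + 1L]
  cm <- cluster_contamination(imputed, rain_m, k = config$k,
                              year_from = final_from)
  utils::write.csv(cbind(data.frame(year = cm$year, period = cm$period,
                                    cluster = cm$labels), cm$X),
                   wpath("cluster_labels.csv"), row.names = FALSE)
  utils::write.csv(cm$profiles, wpath("cluster_profiles.csv"),
                   row.names = FALSE)

  scans <- NULL
  if (!is.null(config$years_weekly) || !is.null(config$weekly_inputs)) {
    note("stage lag scan: weekly panel")
    weekly <- load_panel(config$weekly_inputs, "weekly",
                         config$years_weekly, config$seed + 7L,
                         config$lag_grid)
    wseries <- weekly$series
    write_monitoring(wseries, wpath("monitoring_weekly.csv"))
    write_rainfall(weekly$rain, wpath("rainfall_weekly.csv"))
    wimp <- lapply(wseries, impute_median_by_period)
    scans <- lapply(wimp, function(s) {
      lag_scan(s, weekly$rain, lag_grid = config$lag_grid,
               validation_years = config$validation_years)
    })
    utils::write.csv(lagscan_report(scans), wpath("lagscan.csv"),
                     row.names = FALSE)
  } else {
    note("stage lag scan: no weekly panel configured; skipped")
  }

  manifest <- c(
    sprintf("watermon %s", as.character(utils::packageVersion("watermon"))),
    sprintf("seed: %d", config$seed),
    sprintf("monthly panel: %s",
            if (is.null(config$monthly_inputs))
              sprintf("simulated, %d years", config$years_monthly)
            else config$monthly_inputs$monitoring),
    sprintf("weekly panel: %s",
            if (!is.null(config$weekly_inputs)) config$weekly_inputs$monitoring
            else if (is.null(config$years_weekly)) "none (lag scan skipped)"
            else sprintf("simulated, %d years", config$years_weekly)),
    sprintf("breakpoints: m_max=%s h=%s B=%d",
            ifelse(is.null(config$m_max), "default", config$m_max),
            ifelse(is.null(config$h), "default", config$h),
            config$ci_bootstrap),
    sprintf("periodicity: %d permutations", config$n_permutations),
    sprintf("clustering: k=%d", config$k),
    sprintf("lag scan: grid %s, validation %d years",
            paste(range(config$lag_grid), collapse = "-"),
            config$validation_years))
  writeLines(manifest, wpath("manifest.txt"))

  invisible(list(monthly = monthly, imputed = imputed, breakpoints = fits,
                 periodicity = per_tab, clusters = cm, lagscan = scans))
}

#' Overall non-compliance percentage from printed counts
#'
#' The share of samples positive for at least one indicator among all
#' samples collected, as a percentage rounded to one decimal — the headline
#' summary a long surveillance record is reduced to.
#'
#' @param n_positive,n_total sample counts.
#' @return Percentage (one decimal).
#' @export
noncompliance_pct <- function(n_positive, n_total) {
  if (n_total <= 0 || n_positive < 0 || n_positive > n_total) {
    stop("counts must satisfy 0 <= n_positive <= n_total, n_total > 0")
  }
  round(100 * n_positive / n_total, 1)
}
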