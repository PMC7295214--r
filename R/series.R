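#' @keywords internal
"_PACKAGE"

MARKERS <- c("TC", "EC", "IE", "SSRC", "TOTAL")

#' Periods per year for a given resolution
#'
#' Monthly series use months 1-12; weekly series use fixed-length years of
#' 52 weeks (a 53rd ISO week is folded into week 52 upstream), so that
#' week-of-year indexing is total and seasonal bookkeeping is exact.
#'
#' @param resolution `"monthly"` or `"weekly"`.
#' @return 12 or 52.
#' @export
periods_per_year <- function(resolution = c("monthly", "weekly")) {
  resolution <- match.arg(resolution)
  if (resolution == "monthly") 12L else 52L
}

check_index <- function(year, period, resolution) {
  ppy <- periods_per_year(resolution)
  if (any(period < 1L | period > ppy)) {
    stop("period-of-year out of range 1..", ppy, call. = FALSE)
  }
  lin <- year * ppy + (period - 1L)
  if (length(lin) > 1L && any(diff(lin) != 1L)) {
    bad <- which(diff(lin) != 1L)[1L]
    stop("index must be strictly increasing and gap-free; problem after row ",
         bad, " (year ", year[bad], ", period ", period[bad], ")",
         call. = FALSE)
  }
  invisible(lin)
}

#' Construct a marker monitoring series
#'
#' A `marker_series` holds, for one microbial indicator (TC, EC, IE, SSRC or
#' TOTAL), the per-period number of samples tested, number positive, and the
#' resulting frequency of positive samples, on a gap-free (year, period)
#' index. Periods with no data are flagged `missing` and carry `NA` counts.
#'
#' @param year,period integer vectors defining the (year, period-of-year)
#'   index; must be strictly increasing and gap-free.
#' @param n_tested,n_positive integer counts per period (`NA` where missing).
#' @param marker one of `"TC"`, `"EC"`, `"IE"`, `"SSRC"`, `"TOTAL"`.
#' @param resolution `"monthly"` or `"weekly"`.
#' @param missing optional logical vector; defaults to `is.na(n_tested)`.
#' @return A data frame of class `marker_series` with columns `year`,
#'   `period`, `n_tested`, `n_positive`, `frequency`, `missing`, `imputed`.
#' @export
marker_series <- function(year, period, n_tested, n_positive,
                          marker = c("TC", "EC", "IE", "SSRC", "TOTAL"),
                          resolution = c("monthly", "weekly"),
                          missing = NULL) {
  marker <- match.arg(marker)
  resolution <- match.arg(resolution)
  year <- as.integer(year); period <- as.integer(period)
  stopifnot(length(year) == length(period),
            length(n_tested) == length(year),
            length(n_positive) == length(year))
  check_index(year, period, resolution)
  if (is.null(missing)) missing <- is.na(n_tested) | is.na(n_positive)
  bad <- which(!missing & (is.na(n_tested) | n_tested < 1L))
  if (length(bad)) {
    stop("non-missing period with invalid n_tested at row ", bad[1L],
         " (year ", year[bad[1L]], ", period ", period[bad[1L]], ")",
         call. = FALSE)
  }
  bad <- which(!missing & (n_positive < 0L | n_positive > n_tested))
  if (length(bad)) {
    stop("n_positive outside [0, n_tested] at row ", bad[1L],
         " (year ", year[bad[1L]], ", period ", period[bad[1L]], ")",
         call. = FALSE)
  }
  freq <- ifelse(missing, NA_real_, n_positive / n_tested)
  out <- data.frame(year = year, period = period,
                    n_tested = ifelse(missing, NA_integer_, as.integer(n_tested)),
                    n_positive = ifelse(missing, NA_integer_, as.integer(n_positive)),
                    frequency = freq,
                    missing = as.logical(missing),
                    imputed = FALSE)
  attr(out, "marker") <- marker
  attr(out, "resolution") <- resolution
  class(out) <- c("marker_series", "data.frame")
  out
}

#' @export
print.marker_series <- function(x, ...) {
  cat(sprintf("<marker_series> %s, %s, %d periods (%d missing, %d imputed)\n",
              attr(x, "marker"), attr(x, "resolution"), nrow(x),
              sum(x$missing), sum(x$imputed)))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... ", nrow(x) - 6L, " more rows\n", sep = "")
  invisible(x)
}

#' Construct a rainfall series
#'
#' Per-period cumulative precipitation in mm on the same (year, period) index
#' convention as [marker_series()].
#'
#' @inheritParams marker_series
#' @param rain_mm nonnegative precipitation totals, mm per period.
#' @return A data frame of class `rainfall_series` with columns `year`,
#'   `period`, `rain_mm`.
#' @export
rainfall_series <- function(year, period, rain_mm,
                            resolution = c("monthly", "weekly")) {
  resolution <- match.arg(resolution)
  year <- as.integer(year); period <- as.integer(period)
  stopifnot(length(rain_mm) == length(year))
  check_index(year, period, resolution)
  if (any(rain_mm < 0, na.rm = TRUE)) stop("rain_mm must be nonnegative")
  out <- data.frame(year = year, period = period, rain_mm = as.numeric(rain_mm))
  attr(out, "resolution") <- resolution
  class(out) <- c("rainfall_series", "data.frame")
  out
}

#' @export
print.rainfall_series <- function(x, ...) {
  cat(sprintf("<rainfall_series> %s, %d periods, total %.0f mm\n",
              attr(x, "resolution"), nrow(x), sum(x$rain_mm, na.rm = TRUE)))
  print.data.frame(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("... ", nrow(x) - 6L, " more rows\n", sep = "")
  invisible(x)
}

#' Cumulative-rainfall exposure covariate
#'
#' Builds the distributed-lag covariate C_L(t): the rainfall accumulated over
#' the `lag` periods strictly before t, i.e. sum of rain(t-1), ..., rain(t-L).
#' The window excludes the current period so that the covariate is known
#' before the target period is observed (forecasting use); set
#' `include_current = TRUE` for a window ending at t.
#'
#' @param rain a [rainfall_series()].
#' @param lag integer window length L, in periods (>= 1).
#' @param include_current if `TRUE` the window is t-L+1, ..., t.
#' @return A data frame of class `exposure_series` with columns `year`,
#'   `period`, `exposure`, `valid`; the first L (or L-1) periods have no full
#'   window and are flagged invalid with `NA` exposure.
#' @export
cumulative_exposure <- function(rain, lag, include_current = FALSE) {
  stopifnot(inherits(rain, "rainfall_series"))
  lag <- as.integer(lag)
  if (length(lag) != 1L || is.na(lag) || lag < 1L) {
    stop("lag must be a single integer >= 1")
  }
  n <- nrow(rain)
  if (lag >= n) stop("lag must be smaller than the series length")
  cs <- cumsum(c(0, rain$rain_mm))
  shift <- if (include_current) 0L else 1L
  # window [t - shift - lag + 1, t - shift] via prefix sums
  t <- seq_len(n)
  hi <- t - shift
  lo <- hi - lag
  valid <- lo >= 0L
  expo <- rep(NA_real_, n)
  expo[valid] <- cs[hi[valid] + 1L] - cs[lo[valid] + 1L]
  out <- data.frame(year = rain$year, period = rain$period,
                    exposure = expo, valid = valid)
  attr(out, "lag") <- lag
  attr(out, "include_current") <- include_current
  attr(out, "resolution") <- attr(rain, "resolution")
  class(out) <- c("exposure_series", "data.frame")
  out
}

#' Impute missing frequencies by the period-of-year median
#'
#' Each missing frequency is replaced by the median of the non-missing
#' frequencies observed in the same month (monthly series) or week
#' (weekly series) across all years. Non-missing values are never altered,
#' and imputed periods are flagged in the `imputed` column. Applying the
#' operation twice equals applying it once.
#'
#' @param series a [marker_series()].
#' @return The series with missing frequencies filled and `imputed` set.
#' @export
impute_median_by_period <- function(series) {
  stopifnot(inherits(series, "marker_series"))
  miss <- series$missing
  if (!any(miss)) return(series)
  for (p in unique(series$period[miss])) {
    donors <- series$frequency[series$period == p & !miss]
    donors <- donors[!is.na(donors)]
    if (!length(donors)) {
      stop("cannot impute period-of-year ", p,
           ": no non-missing observation shares it", call. = FALSE)
    }
    sel <- series$period == p & miss
    series$frequency[sel] <- stats::median(donors)
    series$imputed[sel] <- TRUE
  }
  series$missing <- FALSE
  series
}

#' Validate a TOTAL contamination series against its single markers
#'
#' A sample is counted in TOTAL when it is positive for at least one
#' indicator, so per period the TOTAL frequency can be no smaller than any
#' single-marker frequency (on shared samples). Totals cannot be recomputed
#' from per-marker series (sample-level positivity is unavailable), so this
#' checks the invariant on supplied series and returns the TOTAL.
#'
#' @param series_list named list of [marker_series()] including `TOTAL`.
#' @return The validated TOTAL series, invisibly usable downstream.
#' @export
validate_total <- function(series_list) {
  if (!"TOTAL" %in% names(series_list)) stop("series list has no TOTAL entry")
  total <- series_list[["TOTAL"]]
  for (m in setdiff(names(series_list), "TOTAL")) {
    s <- series_list[[m]]
    if (nrow(s) != nrow(total) || any(s$year != total$year) ||
        any(s$period != total$period)) {
      stop("series ", m, " is not aligned with TOTAL")
    }
    ok <- !s$missing & !total$missing
    bad <- which(ok & total$frequency < s$frequency - 1e-12)
    if (length(bad)) {
      stop(sprintf(
        "TOTAL frequency %.4f below %s frequency %.4f at year %d period %d",
        total$frequency[bad[1L]], m, s$frequency[bad[1L]],
        total$year[bad[1L]], total$period[bad[1L]]), call. = FALSE)
    }
  }
  total
}

#' Read monitoring records from delimited text
#'
#' Expects a comma-separated file with header `year,period` followed by
#' `<MARKER>_tested,<MARKER>_positive` column pairs (markers among TC, EC,
#' IE, SSRC, TOTAL). Blank cells mark missing periods.
#'
#' @param path file path.
#' @param resolution `"monthly"`, `"weekly"`, or `NULL` to infer from the
#'   largest period-of-year present (> 12 implies weekly).
#' @return Named list of [marker_series()].
#' @export
read_monitoring <- function(path, resolution = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!all(c("year", "period") %in% names(df))) {
    stop("monitoring file must have 'year' and 'period' columns")
  }
  if (is.null(resolution)) {
    resolution <- if (max(df$period) > 12L) "weekly" else "monthly"
  }
  tested_cols <- grep("_tested$", names(df), value = TRUE)
  markers <- sub("_tested$", "", tested_cols)
  unknown <- setdiff(markers, MARKERS)
  if (length(unknown)) stop("unknown marker column(s): ",
                            paste(unknown, collapse = ", "))
  out <- list()
  for (m in markers) {
    pc <- paste0(m, "_positive")
    if (!pc %in% names(df)) stop("missing column ", pc)
    out[[m]] <- marker_series(df$year, df$period,
                              df[[paste0(m, "_tested")]], df[[pc]],
                              marker = m, resolution = resolution)
  }
  out
}

#' Write monitoring records to delimited text
#'
#' Inverse of [read_monitoring()]: missing periods become blank cells and
#' the round trip preserves values and missingness flags.
#'
#' @param series_list named list of [marker_series()] on a common index.
#' @param path file path.
#' @export
write_monitoring <- function(series_list, path) {
  stopifnot(length(series_list) >= 1L)
  base <- series_list[[1L]]
  df <- data.frame(year = base$year, period = base$period)
  for (m in names(series_list)) {
    s <- series_list[[m]]
    if (nrow(s) != nrow(base)) stop("series ", m, " not aligned")
    df[[paste0(m, "_tested")]] <- s$n_tested
    df[[paste0(m, "_positive")]] <- s$n_positive
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}

#' Read / write a rainfall series
#'
#' Comma-separated file with header `year,period,rain_mm`.
#'
#' @param path file path.
#' @param resolution `"monthly"`, `"weekly"`, or `NULL` to infer.
#' @return [rainfall_series()].
#' @export
read_rainfall <- function(path, resolution = NULL) {
  df <- utils::read.csv(path)
  if (!all(c("year", "period", "rain_mm") %in% names(df))) {
    stop("rainfall file must have columns year, period, rain_mm")
  }
  if (is.null(resolution)) {
    resolution <- if (max(df$period) > 12L) "weekly" else "monthly"
  }
  rainfall_series(df$year, df$period, df$rain_mm, resolution = resolution)
}

#' @rdname read_rainfall
#' @param rain a [rainfall_series()] to write.
#' @export
write_rainfall <- function(rain, path) {
  utils::write.csv(as.data.frame(rain)[c("year", "period", "rain_mm")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Wet/dry season of a period-of-year
#'
#' Antananarivo's wet season runs November-April (weeks 41-13, wrapping over
#' new year) and the dry season May-September (weeks 14-40). October, the
#' transition month, is classed wet, consistent with the week-41 boundary
#' falling in early October.
#'
#' @param period period-of-year (1-12 months or 1-52 weeks).
#' @param resolution `"monthly"` or `"weekly"`.
#' @return Character vector `"wet"`/`"dry"`.
#' @export
season_of <- function(period, resolution = c("monthly", "weekly")) {
  resolution <- match.arg(resolution)
  if (resolution == "monthly") {
    ifelse(period >= 5 & period <= 9, "dry", "wet")
  } else {
    ifelse(period >= 14 & period <= 40, "dry", "wet")
  }
}
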