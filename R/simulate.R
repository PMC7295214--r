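# Synthetic monitoring-data generator: rainfall with annual seasonality,
# binomial contamination counts with planted regime shifts, a month-of-year
# effect, and a lagged cumulative-rainfall effect. Gives every downstream
# stage (breakpoints, periodicity, clustering, lag scan) a known truth.

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

inv_logit <- function(x) 1 / (1 + exp(-x))

#' Simulation configuration
#'
#' Bundles and validates the parameters of the synthetic monitoring-data
#' generator. Defaults emulate the climate and contamination structure of a
#' long-running drinking-water survey in a subtropical highland city:
#' annual rainfall around 1600 mm peaking in January (monthly means above
#' 300 mm) with a nearly dry June (below 10 mm), a piecewise-constant
#' contamination baseline with three regime shifts over 32 years (period
#' means near 4.7%, 1.1%, 4.2% and 9.5%), a month-of-year effect peaking in
#' the wet season, and a contamination response to rainfall accumulated over
#' the `lag_true` preceding periods.
#'
#' @param years series length in years.
#' @param resolution `"monthly"` or `"weekly"`.
#' @param seed integer seed; the generator is a pure function of the config.
#' @param start_year first calendar year label.
#' @param rain_annual_mean expected annual rainfall total, mm.
#' @param rain_peak_month calendar month of the rainfall maximum.
#' @param rain_amplitude seasonality sharpness: the seasonal profile is
#'   proportional to `((1 + cos(2*pi*(p - peak)/P))/2)^rain_amplitude`;
#'   0 gives a flat profile, the default 2 reproduces January means above
#'   300 mm together with a June mean below 10 mm at 1600 mm/year.
#' @param rain_noise_shape gamma shape of the multiplicative rainfall noise
#'   (mean 1); `Inf` disables noise.
#' @param baseline_logit vector of per-segment baseline contamination levels
#'   on the logit scale; one more entry than `break_times`.
#' @param break_times strictly increasing interior period indices at which
#'   the baseline shifts (first period of the new segment).
#' @param lag_true length, in periods, of the cumulative-rainfall window
#'   that truly drives contamination (default 4 weekly, 1 monthly).
#' @param effect_beta effect of cumulative rainfall, logit units per mm of
#'   exposure above its seasonal expectation (default 0.004 weekly,
#'   0.002 monthly).
#' @param month_effect_amplitude amplitude (logit units) of the cosine
#'   period-of-year effect, peaking at `rain_peak_month`.
#' @param n_tested_per_period samples tested per period: a single count or a
#'   `c(min, max)` range sampled uniformly. Defaults to 20 per week
#'   (4 sampling points per day, 5 days a week) and 85 per month.
#' @param missing_rate Bernoulli missingness rate used by
#'   [inject_missing()]; defaults 0.0641 monthly / 0.1869 weekly, matching
#'   typical archival gaps in long monitoring records.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(years = 32L,
                       resolution = c("monthly", "weekly"),
                       seed = 1L,
                       start_year = 1986L,
                       rain_annual_mean = 1600,
                       rain_peak_month = 1L,
                       rain_amplitude = 2,
                       rain_noise_shape = 6,
                       baseline_logit = NULL,
                       break_times = NULL,
                       lag_true = NULL,
                       effect_beta = NULL,
                       month_effect_amplitude = 0.5,
                       n_tested_per_period = NULL,
                       missing_rate = NULL) {
  resolution <- match.arg(resolution)
  ppy <- periods_per_year(resolution)
  n <- as.integer(years) * ppy
  if (is.null(break_times)) {
    break_times <- if (resolution == "monthly" && years >= 28) {
      # shifts after ~5, ~19 and ~26 years, echoing a 4-regime history
      as.integer(round(c(5, 19, 26.2) * 12))
    } else integer(0)
  }
  if (is.null(baseline_logit)) {
    baseline_logit <- if (length(break_times) == 3L) {
      stats::qlogis(c(0.047, 0.011, 0.042, 0.095))
    } else rep(stats::qlogis(0.04), length(break_times) + 1L)
  }
  if (is.null(n_tested_per_period)) {
    n_tested_per_period <- if (resolution == "weekly") 20L else 85L
  }
  if (is.null(missing_rate)) {
    missing_rate <- if (resolution == "weekly") 0.1869 else 0.0641
  }
  if (is.null(lag_true)) {
    lag_true <- if (resolution == "weekly") 4L else 1L
  }
  if (is.null(effect_beta)) {
    effect_beta <- if (resolution == "weekly") 0.004 else 0.002
  }
  break_times <- as.integer(break_times)
  if (length(break_times)) {
    if (any(diff(break_times) <= 0L)) stop("break_times must be strictly increasing")
    if (any(break_times <= 1L) || any(break_times > n - 1L)) {
      stop("break_times must be interior to the series (2..n-1)")
    }
  }
  if (length(baseline_logit) != length(break_times) + 1L) {
    stop("baseline_logit must have one more entry than break_times")
  }
  lag_true <- as.integer(lag_true)
  if (lag_true < 1L) stop("lag_true must be >= 1")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0,1)")
  if (any(n_tested_per_period < 1L)) stop("n_tested_per_period must be >= 1")
  if (rain_amplitude < 0) stop("rain_amplitude must be >= 0")
  cfg <- list(years = as.integer(years), resolution = resolution,
              seed = as.integer(seed), start_year = as.integer(start_year),
              rain_annual_mean = rain_annual_mean,
              rain_peak_month = as.integer(rain_peak_month),
              rain_amplitude = rain_amplitude,
              rain_noise_shape = rain_noise_shape,
              baseline_logit = baseline_logit,
              break_times = break_times,
              lag_true = lag_true, effect_beta = effect_beta,
              month_effect_amplitude = month_effect_amplitude,
              n_tested_per_period = n_tested_per_period,
              missing_rate = missing_rate)
  class(cfg) <- "sim_config"
  cfg
}

# period-of-year seasonal weights, normalised to sum to 1 over a year
seasonal_weights <- function(ppy, peak_period, amplitude) {
  p <- seq_len(ppy)
  w <- ((1 + cos(2 * pi * (p - peak_period) / ppy)) / 2)^amplitude
  w / sum(w)
}

peak_period_of <- function(cfg) {
  ppy <- periods_per_year(cfg$resolution)
  as.integer(round((cfg$rain_peak_month - 1) * ppy / 12)) + 1L
}

# (year, period) labels for linear indices, counting backwards before the
# first period of start_year when idx <= 0 (warm-up periods)
index_labels <- function(idx0, n, start_year, ppy) {
  lin <- seq.int(idx0, length.out = n) - 1L   # 0-based offset from year start
  year <- start_year + lin %/% ppy
  period <- lin %% ppy + 1L
  list(year = as.integer(year), period = as.integer(period))
}

#' Generate a synthetic rainfall series
#'
#' Expected rainfall follows the seasonal profile of [sim_config()] scaled so
#' the expected annual total equals `rain_annual_mean`; per-period noise is
#' multiplicative gamma with mean 1. `warmup` extra periods are prepended
#' (labelled with the preceding year) so that lagged cumulative-rainfall
#' covariates have a full window from the first contamination period.
#'
#' @param config a [sim_config()].
#' @param warmup number of warm-up periods to prepend; defaults to
#'   `config$lag_true`.
#' @return A [rainfall_series()] of `warmup + years * P` periods.
#' @export
gen_rainfall <- function(config, warmup = config$lag_true) {
  stopifnot(inherits(config, "sim_config"))
  ppy <- periods_per_year(config$resolution)
  n <- config$years * ppy + warmup
  lab <- index_labels(1L - warmup, n, config$start_year, ppy)
  w <- seasonal_weights(ppy, peak_period_of(config), config$rain_amplitude)
  mu <- config$rain_annual_mean * w[lab$period]
  rain <- with_seed(config$seed, {
    if (is.finite(config$rain_noise_shape)) {
      mu * stats::rgamma(n, shape = config$rain_noise_shape,
                         rate = config$rain_noise_shape)
    } else mu
  })
  rainfall_series(lab$year, lab$period, rain, resolution = config$resolution)
}

# piecewise-constant baseline on the logit scale
baseline_at <- function(t, break_times, levels) {
  seg <- findInterval(t, c(1L, break_times), rightmost.closed = FALSE)
  levels[seg]
}

contamination_probs <- function(rain, config) {
  ppy <- periods_per_year(config$resolution)
  n <- config$years * ppy
  if (nrow(rain) < n + config$lag_true) {
    stop("rainfall series must cover the simulation horizon plus ",
         config$lag_true, " warm-up periods (have ", nrow(rain),
         ", need ", n + config$lag_true, ")", call. = FALSE)
  }
  expo <- cumulative_exposure(rain, config$lag_true)
  rows <- seq.int(nrow(rain) - n + 1L, nrow(rain))
  if (any(!expo$valid[rows])) stop("internal: exposure window incomplete")
  period <- rain$period[rows]
  b <- baseline_at(seq_len(n), config$break_times, config$baseline_logit)
  m <- config$month_effect_amplitude *
    cos(2 * pi * (period - peak_period_of(config)) / ppy)
  # exposure centred at its expectation so baseline_logit keeps its meaning
  # as the contamination level under typical antecedent rainfall
  c0 <- config$lag_true * config$rain_annual_mean / ppy
  eta <- b + m + config$effect_beta * (expo$exposure[rows] - c0)
  list(p = inv_logit(eta), year = rain$year[rows], period = period,
       exposure = expo$exposure[rows])
}

#' Generate a synthetic contamination marker series
#'
#' For each period t the contamination probability is
#' `plogis(b(t) + m(period(t)) + beta * (C_L(t) - E[C_L]))`: a
#' piecewise-constant baseline shifted at the planted break times, a cosine
#' period-of-year effect, and a linear effect of the rainfall accumulated
#' over the `lag_true` preceding periods, centred at its expectation so the
#' baseline is the level under typical antecedent rainfall. The observed
#' positives are binomial draws out of the per-period number of samples
#' tested.
#'
#' @param rain a [rainfall_series()] covering the simulation horizon plus
#'   `lag_true` warm-up periods (see [gen_rainfall()]).
#' @param config a [sim_config()].
#' @param marker marker label for the output series.
#' @return A [marker_series()] of `years * P` periods.
#' @export
gen_contamination <- function(rain, config, marker = "TC") {
  stopifnot(inherits(config, "sim_config"))
  pr <- contamination_probs(rain, config)
  n <- length(pr$p)
  with_seed(config$seed + 1L, {
    nt <- draw_n_tested(config$n_tested_per_period, n)
    np <- stats::rbinom(n, size = nt, prob = pr$p)
    marker_series(pr$year, pr$period, nt, np, marker = marker,
                  resolution = config$resolution)
  })
}

draw_n_tested <- function(spec, n) {
  if (length(spec) == 1L) rep(as.integer(spec), n)
  else sample(seq.int(spec[1L], spec[2L]), n, replace = TRUE)
}

#' Generate a coherent multi-marker monitoring panel
#'
#' Simulates sample-level positivity: each tested sample is positive for
#' marker m independently with that marker's period probability, and the
#' TOTAL series counts samples positive for at least one marker — so the
#' TOTAL frequency dominates every single-marker frequency by construction,
#' and is below the sum of markers when positives overlap.
#'
#' @param rain a [rainfall_series()] with enough warm-up for the largest
#'   marker lag.
#' @param configs named list of [sim_config()], one per marker (names among
#'   TC, EC, IE, SSRC); all must share years/resolution/start_year.
#' @return Named list of [marker_series()] including `TOTAL`.
#' @export
gen_monitoring <- function(rain, configs) {
  stopifnot(length(configs) >= 1L, !is.null(names(configs)))
  base <- configs[[1L]]
  probs <- lapply(configs, function(cfg) contamination_probs(rain, cfg)$p)
  ref <- contamination_probs(rain, base)
  n <- length(ref$p)
  with_seed(base$seed + 2L, {
    nt <- draw_n_tested(base$n_tested_per_period, n)
    counts <- matrix(0L, n, length(configs),
                     dimnames = list(NULL, names(configs)))
    total <- integer(n)
    for (t in seq_len(n)) {
      pos <- vapply(probs, function(p) stats::runif(nt[t]) < p[t],
                    logical(nt[t]))
      if (nt[t] == 1L) pos <- matrix(pos, nrow = 1L)
      counts[t, ] <- colSums(pos)
      total[t] <- sum(rowSums(pos) > 0L)
    }
    out <- lapply(names(configs), function(m) {
      marker_series(ref$year, ref$period, nt, counts[, m], marker = m,
                    resolution = base$resolution)
    })
    names(out) <- names(configs)
    out$TOTAL <- marker_series(ref$year, ref$period, nt, total,
                               marker = "TOTAL", resolution = base$resolution)
    out
  })
}

#' Mask periods at random to emulate archival gaps
#'
#' Flags each period missing independently with probability `rate`, blanking
#' the exported counts and frequencies. The pre-masking values are kept in
#' the `"truth"` attribute so imputation and recovery can be scored.
#'
#' @param series a [marker_series()].
#' @param rate masking probability in `[0, 1)`.
#' @param seed integer seed.
#' @param ensure_donor if `TRUE`, masks that would blank every occurrence
#'   of some period-of-year are redrawn (rejection sampling), so the
#'   median-by-period imputation rule always has a donor. Short panels at
#'   high masking rates need this; the marginal rate is essentially
#'   unchanged.
#' @return The masked series with attribute `truth` (the original columns).
#' @export
inject_missing <- function(series, rate, seed = 1L, ensure_donor = FALSE) {
  stopifnot(inherits(series, "marker_series"))
  if (rate < 0 || rate >= 1) stop("rate must be in [0, 1)")
  if (rate == 0) return(series)
  mask <- with_seed(seed, {
    for (try in 1:100) {
      m <- stats::runif(nrow(series)) < rate
      if (!ensure_donor) break
      blanked <- m | series$missing
      if (all(tapply(!blanked, series$period, any))) break
      m <- NULL
    }
    if (is.null(m)) stop("could not draw a mask leaving a donor in every ",
                         "period-of-year at rate ", rate)
    m
  })
  truth <- as.data.frame(series)[c("year", "period", "n_tested",
                                   "n_positive", "frequency")]
  series$n_tested[mask] <- NA_integer_
  series$n_positive[mask] <- NA_integer_
  series$frequency[mask] <- NA_real_
  series$missing <- series$missing | mask
  attr(series, "truth") <- truth
  series
}
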