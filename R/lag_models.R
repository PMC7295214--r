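# Distributed-lag ARIMA comparison: a naive week-of-year-mean benchmark, an
# ARIMA with no covariate, and ARIMA-X models adjusted on L-period
# cumulative rainfall with L scanned over a grid and selected by rolling
# one-step-ahead cross-validated RMSE on a held-out window. Orders are
# chosen by a stepwise BIC search (KPSS-based differencing), the covariate
# contribution is tested by a nested likelihood ratio, and residual
# whiteness by a Ljung-Box portmanteau test.

#' Root mean square error
#'
#' @param predictions,observations equal-length numeric vectors, no `NA`.
#' @return `sqrt(mean((predictions - observations)^2))`.
#' @export
rmse <- function(predictions, observations) {
  if (!length(predictions)) stop("empty prediction vector")
  if (length(predictions) != length(observations)) {
    stop("predictions and observations differ in length")
  }
  if (anyNA(predictions) || anyNA(observations)) stop("NA in RMSE input")
  sqrt(mean((predictions - observations)^2))
}

#' Naive seasonal-mean forecast
#'
#' Predicts the value at (year y, period w) by the mean of the non-missing
#' observations at the same period-of-year in all earlier years — the
#' benchmark any covariate model must beat to be relevant.
#'
#' @param series a [marker_series()].
#' @param targets integer row indices of the periods to predict.
#' @return Numeric predictions, one per target.
#' @export
naive_forecast <- function(series, targets) {
  stopifnot(inherits(series, "marker_series"))
  preds <- numeric(length(targets))
  missing_hist <- integer(0)
  for (i in seq_along(targets)) {
    t <- targets[i]
    hist <- series$frequency[series$period == series$period[t] &
                             series$year < series$year[t] &
                             !series$missing]
    hist <- hist[!is.na(hist)]
    if (!length(hist)) {
      missing_hist <- c(missing_hist, series$period[t])
    } else {
      preds[i] <- mean(hist)
    }
  }
  if (length(missing_hist)) {
    stop("no prior-year observation for period(s) ",
         paste(unique(missing_hist), collapse = ", "), call. = FALSE)
  }
  preds
}

# KPSS statistic for level stationarity (Bartlett long-run variance,
# short truncation l = 4 (n/100)^(1/4)); 5% critical value 0.463
kpss_stat <- function(x) {
  n <- length(x)
  e <- x - mean(x)
  S <- cumsum(e)
  l <- trunc(4 * (n / 100)^0.25)
  g0 <- sum(e^2) / n
  lrv <- g0
  for (j in seq_len(l)) {
    lrv <- lrv + 2 * (1 - j / (l + 1)) * sum(e[1:(n - j)] * e[(j + 1):n]) / n
  }
  sum(S^2) / (n^2 * lrv)
}

#' Differencing order by repeated KPSS tests
#'
#' Differences the series until the KPSS level-stationarity statistic drops
#' below its 5% critical value (0.463), up to `max_d` times.
#'
#' @param x numeric series.
#' @param max_d maximum differencing order.
#' @return Integer differencing order d.
#' @export
ndiffs_kpss <- function(x, max_d = 2L) {
  d <- 0L
  while (d < max_d && kpss_stat(x) > 0.463) {
    x <- diff(x)
    d <- d + 1L
  }
  d
}

try_arima <- function(y, order, const, xreg = NULL, fixed = NULL) {
  include_mean <- const && order[2L] == 0L
  fit <- tryCatch(
    suppressWarnings(stats::arima(y, order = order, xreg = xreg,
                                  include.mean = include_mean,
                                  fixed = fixed,
                                  transform.pars = is.null(fixed),
                                  method = "CSS-ML")),
    error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$loglik)) return(NULL)
  fit
}

wrap_arima <- function(fit, y, order, const, nx) {
  n_eff <- fit$nobs
  k <- length(fit$coef) + 1L            # + sigma^2
  bic <- -2 * fit$loglik + k * log(n_eff)
  out <- list(order = order, include_constant = const && order[2L] == 0L,
              coefficients = fit$coef, sigma2 = fit$sigma2,
              log_likelihood = fit$loglik, bic = bic,
              aic = fit$aic, n_eff = n_eff, n_regressors = nx,
              residuals = as.numeric(stats::residuals(fit)),
              model = fit)
  out$fitted_values <- y - out$residuals
  class(out) <- "wm_arima"
  out
}

#' @export
print.wm_arima <- function(x, ...) {
  cat(sprintf("<wm_arima> ARIMA(%d,%d,%d)%s%s  logL = %.2f  BIC = %.2f\n",
              x$order[1], x$order[2], x$order[3],
              if (x$include_constant) " + constant" else "",
              if (x$n_regressors > 0) sprintf(" + %d regressor(s)",
                                              x$n_regressors) else "",
              x$log_likelihood, x$bic))
  if (length(x$coefficients)) print(round(x$coefficients, 4))
  invisible(x)
}

#' Fit an ARIMA model, with optional stepwise BIC order selection
#'
#' With `order = "auto"`, the differencing order is chosen by repeated KPSS
#' tests and (p, q, constant) by a stepwise neighbourhood search: starting
#' from (0,0), (1,0), (0,1) and (2,2), the current best model is perturbed
#' by one step in p and/or q and by toggling the constant, any BIC
#' improvement is accepted, and the search stops at a local minimum
#' (p, q capped at 5). An exogenous regressor enters as a linear term.
#' BIC is `-2 logL + k log(n_eff)` with k counting AR, MA, constant,
#' regression coefficients and the innovation variance.
#'
#' @param y numeric series, no `NA`.
#' @param xreg optional numeric vector/matrix of exogenous regressors
#'   aligned with `y`; a constant column is an error.
#' @param order `"auto"` or a fixed `c(p, d, q)`.
#' @param include_constant force the constant in/out (`NULL` = part of the
#'   search for `"auto"`, `TRUE` for fixed orders with d = 0).
#' @param max_p,max_q,max_d search caps.
#' @return Object of class `wm_arima`.
#' @export
fit_arima <- function(y, xreg = NULL, order = "auto",
                      include_constant = NULL,
                      max_p = 5L, max_q = 5L, max_d = 2L) {
  y <- as.numeric(y)
  if (anyNA(y)) stop("y must not contain NA")
  if (!is.null(xreg)) {
    xreg <- as.matrix(xreg)
    if (is.null(colnames(xreg))) {
      colnames(xreg) <- paste0("xreg", seq_len(ncol(xreg)))
    }
    if (nrow(xreg) != length(y)) stop("xreg not aligned with y")
    if (anyNA(xreg)) stop("xreg must not contain NA (use the valid window)")
    if (any(apply(xreg, 2L, stats::sd) < 1e-12)) {
      stop("near-singular regressor: a column of xreg is constant")
    }
  }
  nx <- if (is.null(xreg)) 0L else ncol(xreg)
  if (!identical(order, "auto")) {
    order <- as.integer(order)
    stopifnot(length(order) == 3L)
    const <- if (is.null(include_constant)) order[2L] == 0L else include_constant
    fit <- try_arima(y, order, const, xreg)
    if (is.null(fit)) {
      stop(sprintf("ARIMA(%d,%d,%d) did not converge", order[1L], order[2L],
                   order[3L]))
    }
    return(wrap_arima(fit, y, order, const, nx))
  }
  d <- ndiffs_kpss(y, max_d = max_d)
  consts <- if (!is.null(include_constant)) include_constant
            else if (d == 0L) c(TRUE, FALSE) else FALSE
  tried <- new.env(parent = emptyenv())
  eval_spec <- function(p, q, const) {
    key <- paste(p, q, const)
    if (!is.null(tried[[key]])) return(tried[[key]])
    fit <- try_arima(y, c(p, d, q), const, xreg)
    res <- if (is.null(fit)) list(bic = Inf)
           else wrap_arima(fit, y, c(p, d, q), const, nx)
    tried[[key]] <- res
    res
  }
  best <- list(bic = Inf)
  best_pqc <- NULL
  for (pq in list(c(0L, 0L), c(1L, 0L), c(0L, 1L), c(2L, 2L))) {
    for (cst in consts) {
      cand <- eval_spec(pq[1L], pq[2L], cst)
      if (cand$bic < best$bic) { best <- cand; best_pqc <- c(pq, cst) }
    }
  }
  if (is.null(best_pqc)) stop("no ARIMA specification converged")
  repeat {
    p <- best_pqc[1L]; q <- best_pqc[2L]; cst <- as.logical(best_pqc[3L])
    moves <- list(c(p + 1L, q), c(p - 1L, q), c(p, q + 1L), c(p, q - 1L),
                  c(p + 1L, q + 1L), c(p - 1L, q - 1L))
    improved <- FALSE
    for (mv in moves) {
      if (mv[1L] < 0L || mv[2L] < 0L || mv[1L] > max_p || mv[2L] > max_q) next
      cand <- eval_spec(mv[1L], mv[2L], cst)
      if (cand$bic < best$bic) {
        best <- cand; best_pqc <- c(mv, cst); improved <- TRUE
      }
    }
    if (length(consts) > 1L) {
      cand <- eval_spec(p, q, !cst)
      if (cand$bic < best$bic) {
        best <- cand; best_pqc <- c(p, q, !cst); improved <- TRUE
      }
    }
    if (!improved) break
  }
  best
}

# one-step-ahead predictions over the whole series with all parameters
# frozen at `fit`'s estimates: re-running the Kalman filter on the full
# series with fixed coefficients yields exactly the rolling forecasts of a
# frozen model whose state updates each step
one_step_predictions <- function(fit, y_full, xreg_full = NULL) {
  stopifnot(inherits(fit, "wm_arima"))
  if (!is.null(xreg_full)) {
    xreg_full <- as.matrix(xreg_full)
    colnames(xreg_full) <- names(fit$coefficients)[
      seq.int(length(fit$coefficients) - ncol(xreg_full) + 1L,
              length(fit$coefficients))]
  }
  if (length(fit$coefficients) == 0L) {
    refit <- stats::arima(y_full, order = fit$order, include.mean = FALSE,
                          method = "CSS-ML")
  } else {
    refit <- stats::arima(y_full, order = fit$order, xreg = xreg_full,
                          include.mean = fit$include_constant,
                          fixed = fit$coefficients, transform.pars = FALSE,
                          method = "CSS-ML")
  }
  as.numeric(y_full - stats::residuals(refit))
}

#' Likelihood-ratio test of nested ARIMA models
#'
#' Compares an adjusted model with its reduced version at the same
#' (p, d, q) and constant (the reduced model drops the exogenous
#' regressors). The statistic `2 (logL_adj - logL_red)` is clipped at zero
#' and referred to a chi-square with as many degrees of freedom as dropped
#' regressors.
#'
#' @param adjusted,reduced `wm_arima` fits on the same data.
#' @return List with `statistic`, `df`, `p_value`.
#' @export
lr_test <- function(adjusted, reduced) {
  stopifnot(inherits(adjusted, "wm_arima"), inherits(reduced, "wm_arima"))
  if (!identical(adjusted$order, reduced$order) ||
      !identical(adjusted$include_constant, reduced$include_constant)) {
    stop("models are not nested: orders or constant differ ",
         "(refit the reduced model at the adjusted model's orders)")
  }
  if (adjusted$n_eff != reduced$n_eff) {
    stop("models are fitted on different sample sizes")
  }
  df <- adjusted$n_regressors - reduced$n_regressors
  if (df < 1L) stop("adjusted model adds no regressor over the reduced one")
  stat <- max(0, 2 * (adjusted$log_likelihood - reduced$log_likelihood))
  list(statistic = stat, df = df,
       p_value = stats::pchisq(stat, df, lower.tail = FALSE))
}

#' Ljung-Box portmanteau test on model residuals
#'
#' Tests that residual autocorrelations up to `n_lags` are jointly zero,
#' with degrees of freedom reduced by the number of fitted ARMA parameters.
#'
#' @param residuals numeric residual series.
#' @param n_lags number of autocorrelations pooled (default 10).
#' @param fitdf fitted-parameter correction, typically p + q.
#' @return The p-value.
#' @export
portmanteau <- function(residuals, n_lags = 10L, fitdf = 0L) {
  if (n_lags - fitdf <= 0L) stop("df = n_lags - fitdf must be positive")
  if (length(residuals) <= n_lags + fitdf) {
    stop("residual series too short for ", n_lags, " lags")
  }
  stats::Box.test(residuals, lag = n_lags, type = "Ljung-Box",
                  fitdf = fitdf)$p.value
}

#' Scan cumulative-rainfall lags with ARIMA cross-validation
#'
#' For each lag L in the grid, builds the L-period cumulative-rainfall
#' covariate, fits an ARIMA-X on the pre-validation window, and scores
#' rolling one-step-ahead forecasts (parameters frozen, state updated each
#' step) over the final `validation_years` years. The best lag minimises
#' the validation RMSE (ties to the smaller lag). The same window and
#' targets score the naive seasonal-mean benchmark and the no-covariate
#' ARIMA, the covariate's contribution is tested by a nested likelihood
#' ratio at the adjusted model's orders, and residual whiteness by a
#' Ljung-Box test.
#'
#' Orders are auto-selected once on the no-covariate training fit and
#' reused across lags, keeping per-lag BICs comparable; set
#' `auto_per_lag = TRUE` to re-run the stepwise search at every lag.
#'
#' @param series an imputed (complete) [marker_series()].
#' @param rain a [rainfall_series()] covering the series index plus at
#'   least `max(lag_grid)` warm-up periods before it.
#' @param lag_grid candidate lags, in periods (default 1:10).
#' @param validation_years length of the held-out window, years.
#' @param order `"auto"` or fixed `c(p, d, q)` used for all models.
#' @param auto_per_lag re-select orders for each lag.
#' @param n_lags_lb Ljung-Box pooling lags.
#' @return Object of class `lagscan_result`.
#' @export
lag_scan <- function(series, rain, lag_grid = 1:10, validation_years = 2L,
                     order = "auto", auto_per_lag = FALSE, n_lags_lb = 10L) {
  stopifnot(inherits(series, "marker_series"),
            inherits(rain, "rainfall_series"))
  ppy <- periods_per_year(attr(series, "resolution"))
  n <- nrow(series)
  nv <- as.integer(validation_years) * ppy
  if (nv >= n) stop("validation window is not shorter than the series")
  y <- series$frequency
  if (anyNA(y)) stop("series has missing values; impute first")
  lag_grid <- sort(unique(as.integer(lag_grid)))
  max_lag <- max(lag_grid)
  # map series rows into the rainfall index (rain may extend earlier)
  ridx <- match(paste(series$year, series$period),
                paste(rain$year, rain$period))
  if (anyNA(ridx)) stop("rainfall series does not cover the monitoring index")
  if (ridx[1L] <= max_lag) {
    stop("rainfall needs ", max_lag, " warm-up periods before the series; ",
         "have ", ridx[1L] - 1L)
  }
  train <- seq_len(n - nv)
  val <- seq.int(n - nv + 1L, n)

  naive_pred <- naive_forecast(series, val)
  naive_rmse <- rmse(naive_pred, y[val])

  fit0 <- fit_arima(y[train], order = order)
  pred0 <- one_step_predictions(fit0, y)
  no_cov_rmse <- rmse(pred0[val], y[val])

  scan <- lapply(lag_grid, function(L) {
    expo <- cumulative_exposure(rain, L)$exposure[ridx]
    ord <- if (auto_per_lag) "auto" else fit0$order
    fitL <- tryCatch(
      fit_arima(y[train], xreg = cbind(exposure = expo[train]),
                order = ord,
                include_constant = if (auto_per_lag) NULL
                                   else fit0$include_constant),
      # the shared order can fail with this covariate; fall back to a
      # stepwise search restricted to converged specifications
      error = function(e) {
        fit_arima(y[train], xreg = cbind(exposure = expo[train]),
                  order = "auto")
      })
    predL <- one_step_predictions(fitL, y, cbind(exposure = expo))
    list(lag = L, fit = fitL, cv_rmse = rmse(predL[val], y[val]),
         bic = fitL$bic, exposure = expo, predictions = predL)
  })
  cv <- vapply(scan, `[[`, numeric(1), "cv_rmse")
  best_i <- which.min(cv)                     # first minimum = smaller lag
  best <- scan[[best_i]]

  reduced <- if (identical(best$fit$order, fit0$order) &&
                 identical(best$fit$include_constant,
                           fit0$include_constant)) fit0
             else fit_arima(y[train], order = best$fit$order,
                            include_constant = best$fit$include_constant)
  lr <- lr_test(best$fit, reduced)
  lb_p <- portmanteau(best$fit$residuals, n_lags = n_lags_lb,
                      fitdf = best$fit$order[1L] + best$fit$order[3L])

  out <- list(marker = attr(series, "marker"),
              lag_grid = lag_grid,
              per_lag = data.frame(lag = lag_grid, cv_rmse = cv,
                                   bic = vapply(scan, `[[`, numeric(1), "bic")),
              best_lag = best$lag,
              adjusted_fit = best$fit,
              no_covariate_fit = fit0,
              bic_adjusted = best$fit$bic,
              bic_no_covariate = fit0$bic,
              lr_statistic = lr$statistic, lr_pvalue = lr$p_value,
              ljung_box_pvalue = lb_p,
              naive_rmse = naive_rmse,
              no_covariate_rmse = no_cov_rmse,
              adjusted_rmse = best$cv_rmse,
              validation = data.frame(
                year = series$year[val], period = series$period[val],
                observed = y[val], naive = naive_pred,
                no_covariate = pred0[val],
                adjusted = best$predictions[val]))
  class(out) <- "lagscan_result"
  out
}

#' @export
print.lagscan_result <- function(x, ...) {
  cat(sprintf("<lagscan_result> %s: best lag = %d periods\n",
              x$marker, x$best_lag))
  cat(sprintf("  BIC adjusted %.2f vs no-covariate %.2f; LR p = %.3g; LB p = %.3g\n",
              x$bic_adjusted, x$bic_no_covariate, x$lr_pvalue,
              x$ljung_box_pvalue))
  cat(sprintf("  RMSE adjusted %.4g | naive %.4g | no-covariate %.4g\n",
              x$adjusted_rmse, x$naive_rmse, x$no_covariate_rmse))
  invisible(x)
}

#' Tabulate lag-scan results across markers
#'
#' One row per marker with the selected lag, BICs of the adjusted and
#' no-covariate models, the likelihood-ratio p-value and the three
#' validation prediction errors.
#'
#' @param results named list of [lag_scan()] results.
#' @return Data frame in the report shape.
#' @export
lagscan_report <- function(results) {
  do.call(rbind, lapply(results, function(r) {
    data.frame(marker = r$marker, lag = r$best_lag,
               bic_model = r$bic_adjusted,
               bic_no_covariate = r$bic_no_covariate,
               lr_pvalue = r$lr_pvalue,
               ljung_box_pvalue = r$ljung_box_pvalue,
               pred_model = r$adjusted_rmse,
               pred_naive = r$naive_rmse,
               pred_no_covariate = r$no_covariate_rmse)
  }))
}
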