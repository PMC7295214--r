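test_that("rmse matches hand values and is homogeneous", {
  expect_equal(rmse(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(rmse(c(1, 0), c(0, 1)), 1)
  set.seed(2)
  p <- runif(10); o <- runif(10)
  expect_equal(rmse(3 * p, 3 * o), 3 * rmse(p, o))
  expect_error(rmse(numeric(0), numeric(0)), "empty")
  expect_error(rmse(1:3, 1:2), "length")
})

test_that("naive forecast is the mean of prior same-period values", {
  # period 3 history (0.0, 0.1, 0.2) -> prediction 0.1 for year 4
  n_pos <- rep(0L, 48)
  n_pos[c(3, 15, 27)] <- c(0L, 1L, 2L)
  s <- marker_series(rep(2001:2004, each = 12), rep(1:12, 4),
                     rep(10L, 48), n_pos, marker = "TC",
                     resolution = "monthly")
  expect_equal(naive_forecast(s, 39L), 0.1)
  # locality: values at other periods do not matter
  s2 <- s; s2$n_positive[c(4, 16)] <- 9L
  s2$frequency[c(4, 16)] <- 0.9
  expect_equal(naive_forecast(s2, 39L), 0.1)
  # no prior history for the first year
  expect_error(naive_forecast(s, 3L), "no prior-year")
})

test_that("the Ljung-Box statistic matches a double-loop evaluation", {
  set.seed(20)
  x <- round(rnorm(20), 3)
  q <- ljung_box_direct(x, 5)
  bx <- stats::Box.test(x, lag = 5, type = "Ljung-Box")
  expect_equal(unname(bx$statistic), q, tolerance = 1e-10)
  expect_equal(portmanteau(x, n_lags = 5, fitdf = 2),
               stats::pchisq(q, df = 3, lower.tail = FALSE),
               tolerance = 1e-10)
  expect_error(portmanteau(x, n_lags = 2, fitdf = 2), "positive")
  expect_error(portmanteau(rnorm(8), n_lags = 10), "too short")
})

test_that("the portmanteau test flags autocorrelated residuals", {
  hits <- 0L
  for (r in 1:50) {
    set.seed(600 + r)
    e <- as.numeric(stats::arima.sim(list(ar = 0.8), 200))
    if (portmanteau(e, 10, 0) < 0.05) hits <- hits + 1L
  }
  expect_gte(hits / 50, 0.95)
})

test_that("likelihood-ratio formula and chi-square reference are exact", {
  mk <- function(ll, nx) structure(
    list(order = c(1L, 0L, 0L), include_constant = TRUE, n_eff = 100L,
         log_likelihood = ll, n_regressors = nx), class = "wm_arima")
  same <- lr_test(mk(50, 1L), mk(50, 0L))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # logL difference 1.9208 sits exactly at the 5% chi-square(1) bound
  crit <- lr_test(mk(51.9208, 1L), mk(50, 0L))
  expect_equal(crit$p_value, 0.05, tolerance = 1e-4)
  expect_error(lr_test(mk(51, 0L), mk(50, 0L)), "no regressor")
  bad <- mk(51, 1L); bad$order <- c(2L, 0L, 0L)
  expect_error(lr_test(bad, mk(50, 0L)), "not nested")
})

test_that("AR(1) parameter and exogenous coefficient are recovered", {
  hits <- 0L
  for (r in 1:30) {
    set.seed(700 + r)
    y <- as.numeric(stats::arima.sim(list(ar = 0.7), 300))
    fit <- fit_arima(y, order = c(1, 0, 0))
    if (abs(fit$coefficients[["ar1"]] - 0.7) < 0.1) hits <- hits + 1L
  }
  expect_gte(hits / 30, 0.9)
  set.seed(750)
  x <- rnorm(300)
  y <- 2 * x + as.numeric(stats::arima.sim(list(ar = 0.5), 300))
  fit <- fit_arima(y, xreg = cbind(x = x), order = c(1, 0, 0))
  expect_lt(abs(fit$coefficients[["x"]] - 2) / 2, 0.2)
  expect_error(fit_arima(y, xreg = cbind(z = rep(1, 300)),
                         order = c(1, 0, 0)), "near-singular")
})

test_that("stepwise selection is parsimonious on white noise", {
  hits <- 0L
  for (r in 1:60) {
    set.seed(800 + r)
    fit <- fit_arima(rnorm(120, mean = 3))
    if (all(fit$order == c(0L, 0L, 0L))) hits <- hits + 1L
  }
  expect_gte(hits / 60, 0.8)
})

test_that("KPSS-based differencing separates stationary from drifting", {
  set.seed(900)
  d_rw <- mean(vapply(1:20, function(r) {
    ndiffs_kpss(cumsum(rnorm(200)))
  }, numeric(1)) >= 1)
  d_wn <- mean(vapply(1:20, function(r) {
    ndiffs_kpss(rnorm(200))
  }, numeric(1)) == 0)
  expect_gte(d_rw, 0.9)
  expect_gte(d_wn, 0.9)
})

test_that("the lag scan recovers a planted cumulative-rainfall lag", {
  sim <- make_lagged_weekly(seed = 424, beta = 0.01)
  scan <- lag_scan(sim$series, sim$rain, order = c(1, 0, 0))
  expect_true(abs(scan$best_lag - 4L) <= 1L)
  expect_lt(scan$adjusted_rmse, scan$naive_rmse)
  expect_equal(scan$per_lag$lag, 1:10)
  expect_equal(scan$best_lag,
               scan$per_lag$lag[which.min(scan$per_lag$cv_rmse)])
  # the three errors are computed on the identical validation window
  expect_equal(nrow(scan$validation), 104L)
  expect_equal(scan$adjusted_rmse,
               rmse(scan$validation$adjusted, scan$validation$observed))
  expect_equal(scan$naive_rmse,
               rmse(scan$validation$naive, scan$validation$observed))
})

test_that("degenerate grids and windows are handled explicitly", {
  sim <- make_lagged_weekly(seed = 77)
  scan <- lag_scan(sim$series, sim$rain, lag_grid = 6L,
                   order = c(1, 0, 0))
  expect_equal(scan$best_lag, 6L)
  expect_error(lag_scan(sim$series, sim$rain, validation_years = 7L),
               "validation window")
  short_rain <- rainfall_series(sim$series$year, sim$series$period,
                                sim$rain$rain_mm[match(
                                  paste(sim$series$year, sim$series$period),
                                  paste(sim$rain$year, sim$rain$period))],
                                "weekly")
  expect_error(lag_scan(sim$series, short_rain, order = c(1, 0, 0)),
               "warm-up")
})

test_that("frozen-parameter filtering reproduces the training one-step fits", {
  set.seed(31)
  y <- as.numeric(stats::arima.sim(list(ar = 0.6), 150)) + 5
  fit <- fit_arima(y[1:100], order = c(1, 0, 0))
  pred <- watermon:::one_step_predictions(fit, y)
  # on the training window the filter reproduces the fitted values
  expect_equal(pred[1:100], fit$fitted_values, tolerance = 1e-8)
  # beyond it, predictions keep tracking the signal
  expect_lt(rmse(pred[101:150], y[101:150]), 2 * sqrt(fit$sigma2))
})
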