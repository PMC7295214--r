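test_that("monitoring files round-trip values and missingness flags", {
  cfg <- sim_config(years = 4L, seed = 11L, break_times = integer(0),
                    baseline_logit = stats::qlogis(0.05))
  rain <- gen_rainfall(cfg)
  s <- gen_contamination(rain, cfg, marker = "TC")
  s <- inject_missing(s, 0.1, seed = 5L)
  path <- withr::local_tempfile(fileext = ".csv")
  write_monitoring(list(TC = s), path)
  back <- read_monitoring(path)[["TC"]]
  expect_equal(back$n_positive, s$n_positive)
  expect_equal(back$n_tested, s$n_tested)
  expect_equal(back$missing, s$missing)
  expect_equal(back$frequency, s$frequency)
  expect_identical(attr(back, "resolution"), "monthly")
})

test_that("invalid counts are rejected with the offending row named", {
  expect_error(
    marker_series(c(2000, 2000), c(1, 2), c(10, 10), c(3, 12),
                  marker = "TC", resolution = "monthly"),
    "row 2.*year 2000, period 2")
  expect_error(
    marker_series(c(2000, 2000), c(1, 3), c(10, 10), c(1, 1),
                  marker = "EC", resolution = "monthly"),
    "gap-free")
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("year,period,XX_tested,XX_positive", "2000,1,10,1"), path)
  expect_error(read_monitoring(path), "unknown marker")
})

test_that("median-by-period imputation fills hand-computed values", {
  # four Januaries (0.10, 0.20, NA, 0.40): median of the rest is 0.20
  n_pos <- rep(0L, 48); n_tst <- rep(10L, 48)
  jan <- seq(1, 48, by = 12)
  n_pos[jan] <- c(1L, 2L, 0L, 4L)
  jun <- seq(6, 48, by = 12)
  s <- marker_series(rep(2001:2004, each = 12), rep(1:12, 4), n_tst, n_pos,
                     marker = "IE", resolution = "monthly")
  s$n_tested[jan[3]] <- NA; s$n_positive[jan[3]] <- NA
  s$frequency[jan[3]] <- NA; s$missing[jan[3]] <- TRUE
  # constant-zero Junes with one gap stay zero
  s$n_tested[jun[2]] <- NA; s$n_positive[jun[2]] <- NA
  s$frequency[jun[2]] <- NA; s$missing[jun[2]] <- TRUE
  imp <- impute_median_by_period(s)
  expect_equal(imp$frequency[jan[3]], 0.20)
  expect_equal(imp$frequency[jun[2]], 0)
  expect_true(imp$imputed[jan[3]])
  # untouched elsewhere, and idempotent
  other <- setdiff(seq_len(48), c(jan[3], jun[2]))
  expect_equal(imp$frequency[other], s$frequency[other])
  expect_identical(impute_median_by_period(imp), imp)
})

test_that("imputation refuses a period-of-year with no donor", {
  s <- marker_series(rep(2001:2002, each = 12), rep(1:12, 2),
                     rep(10L, 24), rep(0L, 24),
                     marker = "EC", resolution = "monthly")
  feb <- c(2, 14)
  s$n_tested[feb] <- NA; s$n_positive[feb] <- NA
  s$frequency[feb] <- NA; s$missing[feb] <- TRUE
  expect_error(impute_median_by_period(s), "no non-missing observation")
})

test_that("cumulative exposure matches hand sums and closed forms", {
  rain <- rainfall_series(rep(2001L, 5), 1:5, c(1, 2, 3, 4, 5), "monthly")
  e3 <- cumulative_exposure(rain, 3)
  expect_equal(e3$exposure, c(NA, NA, NA, 6, 9))
  expect_equal(e3$valid, c(FALSE, FALSE, FALSE, TRUE, TRUE))
  # L = 1 is the series shifted by one period
  e1 <- cumulative_exposure(rain, 1)
  expect_equal(e1$exposure, c(NA, 1, 2, 3, 4))
  # constant rain r gives L * r wherever valid
  rconst <- rainfall_series(rep(2001L, 12), 1:12, rep(7, 12), "monthly")
  e4 <- cumulative_exposure(rconst, 4)
  expect_equal(e4$exposure[e4$valid], rep(28, 8))
  expect_error(cumulative_exposure(rain, 0), "lag")
})

test_that("cumulative exposure is linear in rainfall", {
  set.seed(42)
  r <- runif(30, 0, 100)
  rs <- rainfall_series(2000L + (0:29) %/% 12, (0:29) %% 12 + 1L, r, "monthly")
  for (L in c(1, 3, 6)) {
    a <- 2.5
    e1 <- cumulative_exposure(rs, L)$exposure
    rs2 <- rainfall_series(rs$year, rs$period, a * r, "monthly")
    e2 <- cumulative_exposure(rs2, L)$exposure
    expect_equal(e2, a * e1)
  }
})

test_that("TOTAL dominance is enforced and holds for generated panels", {
  base <- marker_series(rep(2001L, 3), 1:3, rep(100L, 3), c(5L, 0L, 2L),
                        marker = "TC", resolution = "monthly")
  tot_bad <- marker_series(rep(2001L, 3), 1:3, rep(100L, 3), c(3L, 0L, 2L),
                           marker = "TOTAL", resolution = "monthly")
  expect_error(validate_total(list(TC = base, TOTAL = tot_bad)),
               "TOTAL frequency")
  cfgs <- default_marker_configs("weekly", years = 2L, seed = 9L)
  rain <- gen_rainfall(cfgs[[1]], warmup = 10L)
  panel <- gen_monitoring(rain, cfgs)
  expect_silent(validate_total(panel))
  # overlap bound: total never exceeds the sum of single markers
  single_sum <- Reduce(`+`, lapply(panel[c("TC", "EC", "IE", "SSRC")],
                                   function(s) s$n_positive))
  expect_true(all(panel$TOTAL$n_positive <= single_sum))
  expect_true(all(panel$TOTAL$n_positive >=
                    pmax(panel$TC$n_positive, panel$EC$n_positive,
                         panel$IE$n_positive, panel$SSRC$n_positive)))
})
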