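test_that("degenerate seasonality gives a flat series with the right total", {
  cfg <- sim_config(years = 3L, seed = 1L, rain_amplitude = 0,
                    rain_noise_shape = Inf, break_times = integer(0),
                    baseline_logit = stats::qlogis(0.05))
  rain <- gen_rainfall(cfg, warmup = 0L)
  expect_equal(length(unique(round(rain$rain_mm, 10))), 1L)
  expect_equal(sum(rain$rain_mm[rain$year == cfg$start_year]),
               cfg$rain_annual_mean)
})

test_that("default rainfall matches the climatology it emulates", {
  cfg <- sim_config(seed = 4L)
  rain <- gen_rainfall(cfg)
  yr <- tapply(rain$rain_mm[rain$year >= cfg$start_year],
               rain$year[rain$year >= cfg$start_year], sum)
  # annual average above 1500 mm: mean total within +/-20% of 1500
  expect_gt(mean(yr), 1500 * 0.8)
  expect_lt(mean(yr), 1500 * 1.5)
  jan <- mean(rain$rain_mm[rain$period == 1])
  jun <- mean(rain$rain_mm[rain$period == 6])
  expect_gt(jan, jun)
  expect_gt(jan, 250)  # wet-season extreme
  expect_lt(jun, 20)   # dry-season extreme
})

test_that("the generator is a pure function of (config, seed)", {
  cfg <- sim_config(years = 2L, seed = 33L, break_times = integer(0),
                    baseline_logit = stats::qlogis(0.04))
  r1 <- gen_rainfall(cfg); r2 <- gen_rainfall(cfg)
  expect_identical(r1, r2)
  s1 <- gen_contamination(r1, cfg); s2 <- gen_contamination(r2, cfg)
  expect_identical(s1, s2)
  cfg2 <- sim_config(years = 2L, seed = 34L, break_times = integer(0),
                     baseline_logit = stats::qlogis(0.04))
  expect_false(identical(gen_rainfall(cfg2)$rain_mm, r1$rain_mm))
})

test_that("structureless contamination is iid binomial at the baseline", {
  p0 <- 0.06
  cfg <- sim_config(years = 8L, seed = 21L, break_times = integer(0),
                    baseline_logit = stats::qlogis(p0), effect_beta = 0,
                    month_effect_amplitude = 0, n_tested_per_period = 50L)
  s <- gen_contamination(gen_rainfall(cfg), cfg)
  n <- nrow(s)
  se <- sqrt(p0 * (1 - p0) / (50 * n))
  expect_lt(abs(mean(s$frequency) - p0), 3 * se)
  expect_true(all(s$frequency >= 0 & s$frequency <= 1))
  expect_true(all(s$n_positive <= s$n_tested))
})

test_that("the planted lag dominates correlation with a displaced lag", {
  hits <- 0L
  reps <- 100L
  for (r in seq_len(reps)) {
    sim <- make_lagged_weekly(seed = 1000L + r)
    expo <- function(L) {
      e <- cumulative_exposure(sim$rain, L)
      ridx <- match(paste(sim$series$year, sim$series$period),
                    paste(sim$rain$year, sim$rain$period))
      e$exposure[ridx]
    }
    c_true <- cor(sim$series$frequency, expo(4L))
    c_off <- cor(sim$series$frequency, expo(9L))
    if (c_true > c_off) hits <- hits + 1L
  }
  expect_gte(hits / reps, 0.9)
})

test_that("a planted two-segment gap shows in the segment means", {
  cfg <- sim_config(years = 6L, seed = 8L, break_times = 36L,
                    baseline_logit = stats::qlogis(c(0.02, 0.12)),
                    effect_beta = 0, month_effect_amplitude = 0)
  s <- gen_contamination(gen_rainfall(cfg), cfg)
  expect_lt(mean(s$frequency[1:36]), mean(s$frequency[37:72]))
})

test_that("missingness injection is Bernoulli at the requested rate", {
  cfg <- sim_config(years = 32L, seed = 2L)
  s <- gen_contamination(gen_rainfall(cfg), cfg)
  expect_identical(inject_missing(s, 0), s)
  fracs <- vapply(1:200, function(seed) {
    mean(inject_missing(s, 0.0641, seed = seed)$missing)
  }, numeric(1))
  expect_gt(mean(fracs), 0.055)
  expect_lt(mean(fracs), 0.075)
  m1 <- inject_missing(s, 0.2, seed = 7L)
  m2 <- inject_missing(s, 0.2, seed = 7L)
  expect_identical(m1$missing, m2$missing)
  expect_error(inject_missing(s, 1), "rate")
  # masked values are recoverable from the truth attribute
  tr <- attr(m1, "truth")
  expect_equal(tr$frequency[!m1$missing], m1$frequency[!m1$missing])
  expect_false(anyNA(tr$frequency))
})

test_that("simulation configs validate their invariants", {
  expect_error(sim_config(break_times = c(10L, 5L)), "strictly increasing")
  expect_error(sim_config(years = 2L, break_times = 12L,
                          baseline_logit = c(-3, -3, -3)),
               "one more entry")
  expect_error(sim_config(years = 2L, break_times = 30L,
                          baseline_logit = c(-3, -3)),
               "interior")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(lag_true = 0), "lag_true")
  cfg <- sim_config(years = 2L, break_times = integer(0),
                    baseline_logit = -3, lag_true = 8L)
  rain_short <- gen_rainfall(cfg, warmup = 2L)
  expect_error(gen_contamination(rain_short, cfg), "warm-up")
})
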