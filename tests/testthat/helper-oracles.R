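# Independent oracles used against the package's implementations.

# exhaustive search over all admissible placements of m breaks
brute_force_breaks <- function(x, m, h) {
  n <- length(x)
  if (m == 0L) {
    return(list(breaks = integer(0), rss = segment_cost(x, 1L, n)))
  }
  best <- list(breaks = NULL, rss = Inf)
  for (cmb in utils::combn(seq_len(n - 1L), m, simplify = FALSE)) {
    b <- c(0L, cmb, n)
    if (any(diff(b) < h)) next
    rss <- sum(vapply(seq_len(m + 1L), function(s) {
      segment_cost(x, b[s] + 1L, b[s + 1L])
    }, numeric(1)))
    if (rss < best$rss - 1e-12) best <- list(breaks = cmb, rss = rss)
  }
  best
}

# greedy Ward agglomeration recomputed from the definition: at each step
# merge the pair of clusters whose union minimally increases the total
# within-cluster sum of squares; returns the per-step SS increases
greedy_ward_increases <- function(X) {
  wss <- function(rows) {
    if (length(rows) < 2L) return(0)
    sum(scale(X[rows, , drop = FALSE], scale = FALSE)^2)
  }
  groups <- as.list(seq_len(nrow(X)))
  incr <- numeric(nrow(X) - 1L)
  for (s in seq_len(nrow(X) - 1L)) {
    bestd <- Inf
    best <- NULL
    for (i in seq_len(length(groups) - 1L)) {
      for (j in seq.int(i + 1L, length(groups))) {
        d <- wss(c(groups[[i]], groups[[j]])) - wss(groups[[i]]) -
          wss(groups[[j]])
        if (d < bestd - 1e-12) { bestd <- d; best <- c(i, j) }
      }
    }
    incr[s] <- bestd
    groups[[best[1L]]] <- c(groups[[best[1L]]], groups[[best[2L]]])
    groups[[best[2L]]] <- NULL
  }
  incr
}

# Ljung-Box statistic by direct double-loop evaluation of the formula
ljung_box_direct <- function(x, n_lags) {
  n <- length(x)
  xc <- x - mean(x)
  denom <- sum(xc^2)
  q <- 0
  for (k in seq_len(n_lags)) {
    rho <- 0
    for (t in seq.int(k + 1L, n)) rho <- rho + xc[t] * xc[t - k]
    rho <- rho / denom
    q <- q + rho^2 / (n - k)
  }
  n * (n + 2) * q
}

# periodogram intensity at Fourier index k by direct summation
intensity_direct <- function(x, k) {
  n <- length(x)
  xc <- x - mean(x)
  re <- sum(xc * cos(2 * pi * k * seq_len(n) / n))
  im <- sum(xc * sin(2 * pi * k * seq_len(n) / n))
  (re^2 + im^2) / n
}

# small weekly panel with a planted cumulative-rainfall lag
make_lagged_weekly <- function(seed, lag = 4L, beta = 0.008, years = 6L) {
  cfg <- sim_config(years = years, resolution = "weekly", seed = seed,
                    start_year = 2012L, break_times = integer(0),
                    baseline_logit = stats::qlogis(0.04),
                    lag_true = lag, effect_beta = beta,
                    month_effect_amplitude = 0.2)
  rain <- gen_rainfall(cfg, warmup = 10L)
  list(series = gen_contamination(rain, cfg, marker = "SSRC"), rain = rain,
       config = cfg)
}
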