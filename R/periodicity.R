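# Periodogram-based test for a period-of-year (annual) effect: the
# intensity at the Fourier frequency nearest 1/P is compared with its
# distribution over random permutations of the series, which destroys any
# temporal ordering while keeping the marginal distribution.

#' Periodogram of a series
#'
#' Intensities `I(f_k) = |sum_t x_t exp(-2 pi i f_k t)|^2 / n` at the
#' Fourier frequencies `f_k = k/n`, `k = 1..floor(n/2)`, computed on the
#' mean-centred series. A constant series has all intensities zero.
#'
#' @param x numeric series, length >= 4, no `NA`.
#' @return List with `frequency`, `period` (= 1/frequency) and `intensity`.
#' @export
periodogram <- function(x) {
  x <- as.numeric(x)
  n <- length(x)
  if (n < 4L) stop("need at least 4 observations")
  if (anyNA(x)) stop("x must not contain NA")
  xc <- x - mean(x)
  ft <- stats::fft(xc)
  k <- seq_len(n %/% 2L)
  list(frequency = k / n, period = n / k, intensity = Mod(ft[k + 1L])^2 / n)
}

# intensity at one angular frequency for many permutations, vectorised as a
# (B x n) %*% (n) complex product
intensity_at <- function(x, k, n) {
  z <- exp(-2i * pi * k * seq_len(n) / n)
  Mod(sum(x * z))^2 / n
}

#' Permutation test for periodicity at a target period
#'
#' The statistic is the periodogram intensity at the Fourier frequency
#' closest to `1/P`. Its null distribution is obtained by recomputing it on
#' uniformly random permutations of the (centred) series; the p-value uses
#' the add-one rule `p = (1 + #(null >= observed)) / (1 + n_permutations)`,
#' so the smallest attainable p is `1/(n_permutations + 1)` and the test is
#' invariant to shifting or rescaling the series. By default the series is
#' trimmed to the largest multiple of `P` so the target frequency is an
#' exact Fourier frequency and the peak does not leak across bins.
#'
#' @param x numeric series without `NA`.
#' @param P target period in sampling intervals (12 for a month effect in
#'   monthly data, 52 for a week effect in weekly data).
#' @param n_permutations number of random permutations.
#' @param seed integer seed (the test is deterministic given it).
#' @param trim trim `x` to `P * floor(n/P)` observations first.
#' @param alpha significance level for the `significant` flag.
#' @return Object of class `periodicity_test` with the observed intensity,
#'   the frequency used, `p_value` and `significant`.
#' @export
permutation_test <- function(x, P = 12L, n_permutations = 999L, seed = 1L,
                             trim = TRUE, alpha = 0.05) {
  x <- as.numeric(x)
  if (anyNA(x)) stop("x must not contain NA")
  P <- as.integer(P)
  if (P >= length(x)) stop("target period P must be shorter than the series")
  if (trim) x <- x[seq_len(P * (length(x) %/% P))]
  n <- length(x)
  if (n < 2L * P) {
    warning("fewer than two full cycles of P = ", P,
            "; the test has little power")
  }
  xc <- x - mean(x)
  k <- which.min(abs(seq_len(n %/% 2L) / n - 1 / P))
  obs <- intensity_at(xc, k, n)
  null <- with_seed(seed, {
    vapply(seq_len(n_permutations),
           function(b) intensity_at(sample(xc), k, n), numeric(1))
  })
  p <- (1 + sum(null >= obs)) / (1 + n_permutations)
  out <- list(n = n, target_period = P, fourier_frequency = k / n,
              observed_intensity = obs, n_permutations = n_permutations,
              seed = seed, p_value = p, significant = p < alpha,
              alpha = alpha)
  class(out) <- "periodicity_test"
  out
}

#' @export
print.periodicity_test <- function(x, ...) {
  cat(sprintf(
    "<periodicity_test> P = %d (f = %.4f), n = %d, I_obs = %.4g\n",
    x$target_period, x$fourier_frequency, x$n, x$observed_intensity))
  cat(sprintf("p = %.4g (%d permutations)%s\n", x$p_value, x$n_permutations,
              if (x$significant) " *" else ""))
  invisible(x)
}

#' Periodicity p-values per marker and year block
#'
#' Runs the permutation test on each marker restricted to each year block,
#' producing the marker-by-block p-value table used to ask whether a
#' month-of-year (or week-of-year) effect holds within each regime. Blocks
#' shorter than two full cycles are flagged, not dropped.
#'
#' @param series_list named list of [marker_series()] (complete, i.e.
#'   imputed) or plain numeric vectors with an `index` argument.
#' @param blocks named list of `c(first_year, last_year)` ranges.
#' @param P target period; default 12/52 by resolution of the first series.
#' @param n_permutations,seed forwarded to [permutation_test()].
#' @return Data frame: marker, block, first/last year, n, p_value,
#'   significant, note.
#' @export
batch_month_effect <- function(series_list, blocks, P = NULL,
                               n_permutations = 999L, seed = 1L) {
  if (!length(blocks)) {
    return(data.frame(marker = character(0), block = character(0),
                      year_from = integer(0), year_to = integer(0),
                      n = integer(0), p_value = numeric(0),
                      significant = logical(0), note = character(0)))
  }
  if (is.null(names(blocks))) {
    names(blocks) <- vapply(blocks, function(b) paste(b, collapse = "-"),
                            character(1))
  }
  rows <- list()
  for (mk in names(series_list)) {
    s <- series_list[[mk]]
    stopifnot(inherits(s, "marker_series") || inherits(s, "rainfall_series"))
    if (is.null(P)) P <- periods_per_year(attr(s, "resolution"))
    vals <- if (inherits(s, "marker_series")) s$frequency else s$rain_mm
    for (bl in names(blocks)) {
      rg <- blocks[[bl]]
      sel <- s$year >= rg[1L] & s$year <= rg[2L]
      x <- vals[sel]
      if (anyNA(x)) stop("block ", bl, " of ", mk,
                         " has missing values; impute first")
      note <- ""
      if (length(x) < 2L * P) {
        note <- "fewer than two full cycles; not tested"
        pv <- NA_real_
        sig <- NA
      } else {
        tst <- permutation_test(x, P = P, n_permutations = n_permutations,
                                seed = seed)
        pv <- tst$p_value
        sig <- tst$significant
      }
      rows[[length(rows) + 1L]] <-
        data.frame(marker = mk, block = bl, year_from = rg[1L],
                   year_to = rg[2L], n = length(x), p_value = pv,
                   significant = sig, note = note)
    }
  }
  do.call(rbind, rows)
}
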