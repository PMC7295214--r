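# Least-squares multiple-breakpoint estimation for mean-shift models:
# exact dynamic programming over admissible segmentations, BIC selection of
# the number of breaks, and residual-bootstrap confidence intervals for
# break dates. A break index b means the segment ends at observation b and
# a new regime starts at b + 1.

# prefix sums of x and x^2; cost of the constant-mean fit on x[i..j]
segment_prefix <- function(x) {
  list(s = cumsum(c(0, x)), s2 = cumsum(c(0, x^2)))
}

cost_from_prefix <- function(pf, i, j) {
  n <- j - i + 1
  sx <- pf$s[j + 1] - pf$s[i]
  (pf$s2[j + 1] - pf$s2[i]) - sx^2 / n
}

#' Residual sum of squares of a constant-mean segment
#'
#' The least-squares cost of fitting one mean to `x[i..j]`, the building
#' block of the segmentation dynamic programme.
#'
#' @param x numeric series (no `NA`).
#' @param i,j 1-based segment bounds, `i <= j`.
#' @return `sum((x[i:j] - mean(x[i:j]))^2)`.
#' @export
segment_cost <- function(x, i, j) {
  if (i > j || i < 1 || j > length(x)) stop("invalid segment range")
  cost_from_prefix(segment_prefix(x), i, j)
}

#' Optimal placement of m mean-shift breakpoints
#'
#' Finds the global minimiser of the total within-segment residual sum of
#' squares over all placements of `m` breaks with every segment at least
#' `h` observations long, by the Bellman recursion over the last break
#' position (exact optimum in O(n^2) per break, not a greedy search). Ties
#' are broken toward the earliest admissible break.
#'
#' @param x numeric series without `NA`.
#' @param m number of breaks (>= 0).
#' @param h minimum segment length.
#' @return List with `breaks` (indices of segment ends, length `m`) and
#'   `rss` (the minimised residual sum of squares).
#' @export
optimal_breaks <- function(x, m, h) {
  n <- length(x)
  m <- as.integer(m); h <- as.integer(h)
  if (h < 1L) stop("h must be >= 1")
  if (m < 0L) stop("m must be >= 0")
  if (anyNA(x)) stop("x must not contain NA (impute upstream)")
  if ((m + 1L) * h > n) {
    stop("infeasible: ", m, " breaks with minimum segment ", h,
         " need at least ", (m + 1L) * h, " observations, have ", n)
  }
  pf <- segment_prefix(x)
  if (m == 0L) {
    return(list(breaks = integer(0), rss = cost_from_prefix(pf, 1L, n)))
  }
  # F[k, j]: min RSS of x[1..j] split into k segments; A[k, j]: argmin end
  # of segment k-1 (the (k-1)-th break), earliest index on ties
  F <- matrix(Inf, m + 1L, n)
  A <- matrix(NA_integer_, m + 1L, n)
  feas1 <- seq.int(h, n)
  F[1L, feas1] <- cost_from_prefix(pf, 1L, feas1)
  for (k in 2L:(m + 1L)) {
    for (j in seq.int(k * h, n)) {
      b <- seq.int((k - 1L) * h, j - h)     # candidate previous break
      tot <- F[k - 1L, b] + cost_from_prefix(pf, b + 1L, j)
      best <- which.min(tot)                # first minimum = earliest break
      F[k, j] <- tot[best]
      A[k, j] <- b[best]
    }
  }
  breaks <- integer(m)
  j <- n
  for (k in seq.int(m + 1L, 2L)) {
    breaks[k - 1L] <- A[k, j]
    j <- A[k, j]
  }
  list(breaks = breaks, rss = F[m + 1L, n])
}

bic_breaks <- function(n, rss, m) {
  # k(m) = m break dates + (m + 1) segment means + 1 variance = 2m + 2
  n * log(rss / n) + (2 * m + 2) * log(n)
}

#' Fit mean-shift breakpoints with BIC selection of their number
#'
#' Computes the optimal segmentation for every candidate number of breaks
#' `m = 0, ..., m_max` and selects the `m` minimising
#' `BIC(m) = n log(RSS_m / n) + (2m + 2) log(n)` (break dates, segment
#' means and one variance as free parameters; ties go to fewer breaks).
#'
#' @param x numeric series or [marker_series()]/[rainfall_series()] (their
#'   frequency / rain_mm column is used; must be complete).
#' @param m_max largest number of breaks considered; default the most the
#'   trimming allows, capped at 5.
#' @param h minimum segment length; default `floor(0.15 * n)`, the usual
#'   15% trimming.
#' @return An object of class `breakpoint_fit`: candidate table (`m`,
#'   `rss`, `bic`, break positions), `selected_m`, `breaks`,
#'   `segment_means`, and the data for later interval estimation.
#' @export
select_num_breaks <- function(x, m_max = NULL, h = NULL) {
  x <- series_values(x)
  n <- length(x)
  if (is.null(h)) h <- max(1L, floor(0.15 * n))
  h <- as.integer(h)
  feas_max <- n %/% h - 1L
  if (is.null(m_max)) m_max <- max(0L, min(5L, feas_max))
  m_max <- as.integer(m_max)
  if (m_max > feas_max) {
    stop("m_max = ", m_max, " infeasible with h = ", h, " and n = ", n)
  }
  fits <- lapply(0L:m_max, function(m) optimal_breaks(x, m, h))
  rss <- vapply(fits, `[[`, numeric(1), "rss")
  bic <- bic_breaks(n, pmax(rss, .Machine$double.xmin), 0L:m_max)
  sel <- which.min(bic) - 1L                 # first minimum = smallest m
  breaks <- fits[[sel + 1L]]$breaks
  bounds <- c(0L, breaks, n)
  means <- vapply(seq_len(sel + 1L), function(s) {
    mean(x[(bounds[s] + 1L):bounds[s + 1L]])
  }, numeric(1))
  out <- list(x = x, n = n, h = h, m_max = m_max,
              candidates = data.frame(m = 0L:m_max, rss = rss, bic = bic),
              per_m_breaks = lapply(fits, `[[`, "breaks"),
              selected_m = sel, breaks = breaks, segment_means = means,
              ci = NULL, ci_method = NULL)
  class(out) <- "breakpoint_fit"
  out
}

series_values <- function(x) {
  if (inherits(x, "marker_series")) x <- x$frequency
  else if (inherits(x, "rainfall_series")) x <- x$rain_mm
  x <- as.numeric(x)
  if (anyNA(x)) stop("series contains NA; impute missing periods first")
  x
}

#' @export
print.breakpoint_fit <- function(x, ...) {
  cat(sprintf("<breakpoint_fit> n = %d, h = %d, selected m = %d\n",
              x$n, x$h, x$selected_m))
  print(x$candidates, row.names = FALSE)
  if (x$selected_m > 0) {
    cat("breaks at:", paste(x$breaks, collapse = ", "), "\n")
    if (!is.null(x$ci)) {
      for (i in seq_len(nrow(x$ci))) {
        cat(sprintf("  break %d: %d [%d, %d] (%s)\n", i, x$breaks[i],
                    x$ci$lower[i], x$ci$upper[i], x$ci_method))
      }
    }
  }
  cat("segment means:", paste(signif(x$segment_means, 4), collapse = ", "),
      "\n")
  invisible(x)
}

fitted_segments <- function(fit) {
  bounds <- c(0L, fit$breaks, fit$n)
  rep(fit$segment_means, diff(bounds))
}

#' Bootstrap confidence intervals for break dates
#'
#' Residual-resampling bootstrap: residuals from the fitted segmentation are
#' resampled with replacement onto the fitted step function, the breaks are
#' re-estimated on each replicate (same number of breaks, same trimming),
#' and the empirical quantiles of each break position give the interval.
#' Intervals are widened if needed to contain the point estimate.
#'
#' @param fit a [select_num_breaks()] fit with `selected_m >= 1`.
#' @param level confidence level in (0, 1).
#' @param B bootstrap replicates.
#' @param seed integer seed.
#' @return The fit with `ci` (data frame `lower`, `upper` per break) and
#'   `ci_method` filled in.
#' @export
break_confidence_intervals <- function(fit, level = 0.95, B = 199L,
                                       seed = 1L) {
  stopifnot(inherits(fit, "breakpoint_fit"))
  if (fit$selected_m < 1L) stop("no breaks selected; nothing to bound")
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  mu <- fitted_segments(fit)
  res <- fit$x - mu
  m <- fit$selected_m
  boot <- with_seed(seed, {
    vapply(seq_len(B), function(b) {
      xb <- mu + sample(res, fit$n, replace = TRUE)
      optimal_breaks(xb, m, fit$h)$breaks
    }, integer(m))
  })
  boot <- matrix(boot, nrow = m)
  alpha <- (1 - level) / 2
  lo <- apply(boot, 1L, stats::quantile, probs = alpha, type = 1L)
  hi <- apply(boot, 1L, stats::quantile, probs = 1 - alpha, type = 1L)
  fit$ci <- data.frame(lower = as.integer(pmin(lo, fit$breaks)),
                       upper = as.integer(pmax(hi, fit$breaks)))
  fit$ci_method <- sprintf("residual bootstrap (B = %d)", B)
  fit
}

#' Tabulate breakpoint fits across markers as (year, period) dates
#'
#' One row per selected break per marker, with the break date and its
#' confidence bounds mapped back to calendar (year, period) labels.
#'
#' @param fits named list of [breakpoint_fit] objects.
#' @param index data frame with `year` and `period` giving the calendar
#'   label of each series position (shared by all fits).
#' @return Data frame: marker, break number, position, year, period, CI
#'   bounds as positions and labels.
#' @export
breakpoint_report <- function(fits, index) {
  lab <- function(i) sprintf("%d(%d)", index$year[i], index$period[i])
  rows <- lapply(names(fits), function(mk) {
    f <- fits[[mk]]
    if (f$selected_m == 0L) {
      return(data.frame(marker = mk, break_no = NA_integer_,
                        position = NA_integer_, date = NA_character_,
                        ci_lower = NA_character_, ci_upper = NA_character_))
    }
    has_ci <- !is.null(f$ci)
    data.frame(marker = mk, break_no = seq_len(f$selected_m),
               position = f$breaks, date = lab(f$breaks),
               ci_lower = if (has_ci) lab(f$ci$lower) else NA_character_,
               ci_upper = if (has_ci) lab(f$ci$upper) else NA_character_)
  })
  do.call(rbind, rows)
}
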