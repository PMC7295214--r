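# Ward hierarchical clustering of monthly contamination profiles on the
# four active markers (IE, EC, TC, SSRC). Rainfall and total contamination
# are supplementary: they appear in the cluster profiles for interpretation
# but never enter the distances (collinearity of TOTAL with the markers is
# the reason the paper trail of this design excludes it from the metric).

#' Ward linkage tree on marker profiles
#'
#' Agglomerative clustering under Ward's minimum-variance criterion on
#' squared Euclidean distances (heights are on the squared scale, i.e.
#' proportional to the increase in within-cluster sum of squares at each
#' merge). Marker frequencies share the unit "fraction of positive
#' samples", so no standardisation is applied by default.
#'
#' @param X numeric matrix or data frame, observations x active variables.
#' @param standardize z-score columns first.
#' @return An [stats::hclust] tree (method `ward.D` on squared distances).
#' @export
ward_tree <- function(X, standardize = FALSE) {
  X <- as.matrix(X)
  if (anyNA(X)) stop("X contains NA; impute missing periods first")
  if (nrow(X) < 2L) stop("need at least 2 observations")
  if (standardize) X <- scale(X)
  stats::hclust(stats::dist(X)^2, method = "ward.D")
}

#' Cut a linkage tree into k clusters, largest first
#'
#' Labels from cutting the tree at `k` groups, renumbered so that cluster 1
#' is the largest (ties broken by first appearance in the series).
#'
#' @param tree an [stats::hclust] object.
#' @param k number of clusters.
#' @return Integer labels in `1..k`.
#' @export
cut_to_clusters <- function(tree, k = 4L) {
  n <- length(tree$order)
  if (k < 1L || k > n) stop("k must be in 1..", n)
  raw <- stats::cutree(tree, k = k)
  sizes <- tabulate(raw, nbins = k)
  first <- vapply(seq_len(k), function(c) which(raw == c)[1L], integer(1))
  rank <- order(-sizes, first)
  relab <- integer(k)
  relab[rank] <- seq_len(k)
  unname(relab[raw])
}

#' Cluster profiles and composition tables
#'
#' Per-cluster means of the active variables and of the supplementary
#' variables (aligned by row, never used in the clustering itself), plus
#' composition counts by wet/dry season, year and period-of-year.
#'
#' @param labels integer cluster labels.
#' @param X active variables used in the clustering (observations x p).
#' @param supplementary data frame of supplementary variables aligned with
#'   `X` (e.g. rainfall, TOTAL frequency); may be `NULL`.
#' @param year,period calendar labels per observation.
#' @param resolution `"monthly"` or `"weekly"` (for the season split).
#' @return List with `profiles` (cluster x variable means, with sizes) and
#'   `composition` (contingency tables by season, year, period).
#' @export
cluster_profiles <- function(labels, X, supplementary = NULL, year, period,
                             resolution = c("monthly", "weekly")) {
  resolution <- match.arg(resolution)
  X <- as.data.frame(X)
  n <- nrow(X)
  if (length(labels) != n) stop("labels not aligned with observations")
  if (length(year) != n || length(period) != n) {
    stop("year/period labels not aligned with observations")
  }
  vars <- X
  if (!is.null(supplementary)) {
    supplementary <- as.data.frame(supplementary)
    if (nrow(supplementary) != n) {
      stop("supplementary variables not aligned with observations")
    }
    vars <- cbind(X, supplementary)
  }
  cl <- sort(unique(labels))
  prof <- do.call(rbind, lapply(cl, function(c) {
    colMeans(vars[labels == c, , drop = FALSE])
  }))
  profiles <- data.frame(cluster = cl, size = tabulate(labels)[cl], prof)
  season <- season_of(period, resolution)
  composition <- list(
    season = table(cluster = labels, season = season),
    year = table(cluster = labels, year = year),
    period = table(cluster = labels, period = period))
  list(profiles = profiles, composition = composition)
}

#' Cluster monthly contamination profiles end to end
#'
#' Builds the observation matrix from the four single-marker frequencies
#' over a year window (typically the final regime found by breakpoint
#' detection), clusters it with [ward_tree()], cuts at `k`, and attaches
#' rainfall and TOTAL contamination as supplementary profile variables.
#'
#' @param series_list named list of imputed [marker_series()] including the
#'   active markers and optionally `TOTAL`.
#' @param rain optional [rainfall_series()] aligned by (year, period).
#' @param k number of clusters.
#' @param year_from,year_to inclusive year window; default all years.
#' @param markers active markers (default IE, EC, TC, SSRC).
#' @return List of class `cluster_model`: `tree`, `labels`, `X`,
#'   `profiles`, `composition`, `year`, `period`.
#' @export
cluster_contamination <- function(series_list, rain = NULL, k = 4L,
                                  year_from = -Inf, year_to = Inf,
                                  markers = c("IE", "EC", "TC", "SSRC")) {
  miss <- setdiff(markers, names(series_list))
  if (length(miss)) stop("missing marker series: ", paste(miss, collapse = ", "))
  base <- series_list[[markers[1L]]]
  sel <- base$year >= year_from & base$year <= year_to
  X <- sapply(markers, function(m) series_list[[m]]$frequency[sel])
  colnames(X) <- markers
  supp <- NULL
  if (!is.null(rain)) {
    key <- paste(base$year[sel], base$period[sel])
    ridx <- match(key, paste(rain$year, rain$period))
    if (anyNA(ridx)) stop("rainfall series does not cover the cluster window")
    supp <- data.frame(rain_mm = rain$rain_mm[ridx])
  }
  if ("TOTAL" %in% names(series_list)) {
    tot <- series_list[["TOTAL"]]$frequency[sel]
    supp <- if (is.null(supp)) data.frame(TOTAL = tot) else cbind(supp, TOTAL = tot)
  }
  tree <- ward_tree(X)
  labels <- cut_to_clusters(tree, k)
  prof <- cluster_profiles(labels, X, supp, base$year[sel], base$period[sel],
                           resolution = attr(base, "resolution"))
  out <- list(tree = tree, labels = labels, X = X, profiles = prof$profiles,
              composition = prof$composition, year = base$year[sel],
              period = base$period[sel], k = k)
  class(out) <- "cluster_model"
  out
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf("<cluster_model> %d observations, k = %d\n", nrow(x$X), x$k))
  print(x$profiles, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Pair-counting agreement between two labelings, corrected for chance;
#' 1 for identical partitions (up to relabeling), about 0 for independent
#' ones.
#'
#' @param a,b integer label vectors of equal length.
#' @return The adjusted Rand index.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stop("label vectors differ in length")
  tab <- table(a, b)
  n <- length(a)
  sum_ij <- sum(choose(tab, 2))
  sum_i <- sum(choose(rowSums(tab), 2))
  sum_j <- sum(choose(colSums(tab), 2))
  expected <- sum_i * sum_j / choose(n, 2)
  maxi <- (sum_i + sum_j) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
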