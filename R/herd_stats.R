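# Concordance and shape statistics over daily ranks.

#' Kendall's coefficient of concordance over days
#'
#' Measures agreement among the m days (raters) in how they rank the n cows
#' (items): W = 1 when every day produces the same ordering, W near 0 when
#' days are unrelated (E[W] is about 1/m under independence). Each day's
#' vector of daily median ranks is first converted to within-day midranks,
#' because W is defined on rankings; the tie-corrected form is then
#'
#'   W = 12 * S / (m^2 (n^3 - n) - m * sum_j T_j)
#'
#' with S the sum of squared deviations of the cow rank sums from their mean
#' m(n+1)/2 and T_j = sum over tie groups of (t^3 - t) in day j.
#' Significance uses chi-squared = m (n - 1) W on n - 1 degrees of freedom.
#'
#' @param rank_matrix Numeric matrix, days in rows, cows in columns; any
#'   missing cell is an error (resolve gaps upstream).
#' @param ties_correction Apply the tie correction term (default `TRUE`).
#'   With no ties the two variants coincide.
#' @return An object of class `kendall_w`: a list with `W`, `chi2`, `df`,
#'   `p`, `m_days`, `n_cows`, `ties_corrected`.
#' @export
kendalls_w <- function(rank_matrix, ties_correction = TRUE) {
  rank_matrix <- as.matrix(rank_matrix)
  m <- nrow(rank_matrix)
  n <- ncol(rank_matrix)
  if (m < 2 || n < 2) stop("need at least 2 days and 2 cows")
  if (anyNA(rank_matrix)) {
    idx <- which(is.na(rank_matrix), arr.ind = TRUE)[1, ]
    stop("missing cell at day ", idx[1], ", cow ", idx[2])
  }
  ranked <- t(apply(rank_matrix, 1, rank, ties.method = "average"))
  R <- colSums(ranked)
  S <- sum((R - m * (n + 1) / 2)^2)
  T_j <- apply(ranked, 1, function(r) {
    t <- table(r)
    sum(t^3 - t)
  })
  denom <- m^2 * (n^3 - n) - if (ties_correction) m * sum(T_j) else 0
  if (denom <= 0) stop("degenerate input: all cows tied on every day")
  W <- 12 * S / denom
  chi2 <- m * (n - 1) * W
  structure(
    list(W = W, chi2 = chi2, df = n - 1,
         p = stats::pchisq(chi2, df = n - 1, lower.tail = FALSE),
         m_days = m, n_cows = n, ties_corrected = ties_correction),
    class = "kendall_w"
  )
}

#' @export
print.kendall_w <- function(x, ...) {
  cat(sprintf("Kendall's W = %.4f (m = %d days, n = %d cows%s)\n",
              x$W, x$m_days, x$n_cows,
              if (x$ties_corrected) ", ties corrected" else ""))
  cat(sprintf("chi-squared = %.2f, df = %d, p = %.3g\n", x$chi2, x$df, x$p))
  invisible(x)
}

#' Pivot daily ranks to a days-by-cows matrix
#'
#' Helper for [kendalls_w()]: rows are days, columns cows, cells the daily
#' median rank. Missing cow-days stay `NA` and must be resolved by the
#' caller's gap policy before computing W.
#'
#' @param daily Tibble from [daily_median_ranks()].
#' @return Numeric matrix with days as rownames and cow IDs as colnames.
#' @export
daily_rank_matrix <- function(daily) {
  wide <- daily |>
    dplyr::select("cow_id", "day", "median_rank") |>
    tidyr::pivot_wider(names_from = "cow_id", values_from = "median_rank") |>
    dplyr::arrange(.data$day)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- as.character(wide$day)
  m
}

#' Moment skewness
#'
#' Third standardised central moment m3 / m2^(3/2) with moments normalised
#' by n (the moment convention; not bias-corrected). Values beyond +-0.5 are
#' conventionally read as skewed and beyond +-1 as extremely skewed.
#'
#' @param x Numeric vector, length >= 3, non-constant.
#' @param bias_corrected If `TRUE`, apply the usual small-sample adjustment
#'   `sqrt(n(n-1))/(n-2)`. Default `FALSE`.
#' @return Skewness (dimensionless).
#' @export
moment_skewness <- function(x, bias_corrected = FALSE) {
  n <- length(x)
  if (n < 3) stop("need at least 3 values")
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) stop("zero variance: skewness undefined")
  g1 <- mean((x - mean(x))^3) / m2^1.5
  if (bias_corrected) g1 <- g1 * sqrt(n * (n - 1)) / (n - 2)
  g1
}

#' Moment kurtosis (non-excess)
#'
#' Fourth standardised central moment m4 / m2^2, reported on the non-excess
#' scale where a normal distribution sits at 3: above 3 the rank
#' distribution is peaked, below 3 flat.
#'
#' @inheritParams moment_skewness
#' @return Kurtosis (dimensionless, normal = 3).
#' @export
moment_kurtosis <- function(x, bias_corrected = FALSE) {
  n <- length(x)
  if (n < 3) stop("need at least 3 values")
  m2 <- mean((x - mean(x))^2)
  if (m2 == 0) stop("zero variance: kurtosis undefined")
  g2 <- mean((x - mean(x))^4) / m2^2
  if (bias_corrected) {
    g2 <- ((n + 1) * (g2 - 3) + 6) * (n - 1) / ((n - 2) * (n - 3)) + 3
  }
  g2
}

#' Mode of a kernel density estimate
#'
#' Gaussian-kernel density with bandwidth from Silverman's rule of thumb
#' (0.9 min(sd, IQR/1.34) n^(-1/5)), evaluated on a 512-point grid spanning
#' the data plus three bandwidths each side. The peak x is the grid argmax
#' (ties broken to the lower x); the peak y is the density there times 100,
#' i.e. on the percent scale.
#'
#' @param x Numeric vector with at least 2 distinct values.
#' @param bw Bandwidth: a number, or a rule name understood by
#'   [stats::density()] (default `"nrd0"`, Silverman).
#' @param n_grid Grid size (default 512).
#' @param cut Grid extension in bandwidths beyond the data range (default 3).
#' @return A list with `peak_x`, `peak_y_percent`, `bandwidth`.
#' @export
density_peak <- function(x, bw = "nrd0", n_grid = 512, cut = 3) {
  if (length(unique(x)) < 2) stop("degenerate density: all values identical")
  dens <- stats::density(x, bw = bw, kernel = "gaussian", n = n_grid, cut = cut)
  # grid values within float noise of the maximum count as tied; the tie
  # resolves to the lowest x on the ascending grid
  i <- which(dens$y >= max(dens$y) * (1 - 1e-9))[1]
  list(peak_x = dens$x[i], peak_y_percent = 100 * dens$y[i], bandwidth = dens$bw)
}

#' Spearman rank correlation
#'
#' Pearson correlation of midranks (tie-aware).
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return rho in `[-1, 1]`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector: rho undefined")
  stats::cor(x, y, method = "spearman")
}

#' Five-number summary with outlier fences
#'
#' Min, Q1, median, Q3, max (quartiles by linear interpolation, type 7),
#' plus the points outside the Tukey fences Q1 - 1.5 IQR and Q3 + 1.5 IQR.
#' Min and max are taken over all data; the fences only select outliers.
#'
#' @param x Numeric vector, length >= 1.
#' @return A list with `min`, `q1`, `median`, `q3`, `max`, `outliers`.
#' @export
boxplot_summary <- function(x) {
  if (length(x) < 1) stop("need at least 1 value")
  q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  iqr <- q[3] - q[1]
  list(min = min(x), q1 = q[1], median = q[2], q3 = q[3], max = max(x),
       outliers = sort(x[x < q[1] - 1.5 * iqr | x > q[3] + 1.5 * iqr]))
}

#' Per-cow rank-distribution summary
#'
#' One row per cow: moment skewness and kurtosis of its daily median ranks,
#' and the kernel-density peak location and height. This is the table a herd
#' analysis reports next to the density plot.
#'
#' @param daily Tibble from [daily_median_ranks()].
#' @inheritParams density_peak
#' @return Tibble with `cow_id`, `skewness`, `kurtosis`, `peak_x`,
#'   `peak_y_percent`, `bandwidth`.
#' @export
density_summary <- function(daily, bw = "nrd0", n_grid = 512, cut = 3) {
  daily |>
    dplyr::group_by(.data$cow_id) |>
    dplyr::summarise(
      skewness = moment_skewness(.data$median_rank),
      kurtosis = moment_kurtosis(.data$median_rank),
      peak = list(density_peak(.data$median_rank, bw = bw, n_grid = n_grid, cut = cut)),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      peak_x = vapply(.data$peak, `[[`, numeric(1), "peak_x"),
      peak_y_percent = vapply(.data$peak, `[[`, numeric(1), "peak_y_percent"),
      bandwidth = vapply(.data$peak, `[[`, numeric(1), "bandwidth")
    ) |>
    dplyr::select(-"peak")
}
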