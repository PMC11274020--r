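# Ranking core: pairwise distances -> median neighbour distance -> ranks ->
# daily medians -> cumulative curves.

EARTH_RADIUS_M <- 6371008.8

#' Great-circle distance in metres
#'
#' Haversine distance on a sphere of mean radius 6,371,008.8 m. Vectorised
#' over coordinate vectors. At paddock extents (a few km) the spherical
#' approximation is accurate to well under a metre.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (WGS84).
#' @return Distance(s) in metres.
#' @export
haversine_m <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90, na.rm = TRUE) ||
      any(abs(c(lon1, lon2)) > 180, na.rm = TRUE)) {
    stop("coordinates out of range")
  }
  geosphere::distHaversine(cbind(lon1, lat1), cbind(lon2, lat2), r = EARTH_RADIUS_M)
}

# vectorised all-pairs haversine; same sphere as haversine_m()
haversine_matrix <- function(lat, lon) {
  phi <- lat * pi / 180
  lam <- lon * pi / 180
  a <- sin(outer(phi, phi, "-") / 2)^2 +
    outer(cos(phi), cos(phi)) * sin(outer(lam, lam, "-") / 2)^2
  2 * EARTH_RADIUS_M * asin(pmin(sqrt(a), 1))
}

#' Pairwise distance matrix for one interval
#'
#' @param positions Interval positions for a single 15-min interval: a tibble
#'   with `cow_id`, `lat_med`, `lon_med` (one row per cow).
#' @return A symmetric matrix of great-circle distances in metres with zero
#'   diagonal, dimnames set to the cow IDs.
#' @export
interval_distance_matrix <- function(positions) {
  if (nrow(positions) < 2) stop("need at least 2 cows in the interval")
  if (anyDuplicated(positions$cow_id)) stop("duplicate cow_id within interval")
  d <- haversine_matrix(positions$lat_med, positions$lon_med)
  dimnames(d) <- list(positions$cow_id, positions$cow_id)
  d
}

#' Median distance from one cow to its herdmates
#'
#' The cow's proximity-centrality score for the interval: the median of its
#' distances to every other cow present (16 distances in a full 17-cow herd).
#'
#' @param d Distance matrix from [interval_distance_matrix()].
#' @param cow Cow ID (must be present in `d`).
#' @return Median neighbour distance in metres.
#' @export
median_neighbour_distance <- function(d, cow) {
  if (!cow %in% rownames(d)) stop("cow ", cow, " not present in matrix")
  stats::median(d[cow, colnames(d) != cow])
}

#' Rank cows within an interval by median neighbour distance
#'
#' Ascending: rank 1 is the cow closest (in median) to its herdmates, rank
#' `n_present` the farthest. Exact ties receive midranks, preserving the
#' rank-sum invariant `n(n+1)/2`.
#'
#' @param medians Named numeric vector of median neighbour distances, one
#'   entry per cow present.
#' @return Tibble with `cow_id`, `median_distance_m`, `rank`, `n_present`.
#' @export
rank_within_interval <- function(medians) {
  if (length(medians) < 2) stop("need at least 2 cows to rank")
  tibble::tibble(
    cow_id = names(medians),
    median_distance_m = unname(medians),
    rank = rank(unname(medians), ties.method = "average"),
    n_present = length(medians)
  )
}

#' Per-interval median neighbour distances and ranks for a whole data set
#'
#' Runs the distance-matrix / median / rank chain over every (day, interval)
#' cell of an interval-position table.
#'
#' @param intervals Interval positions from [bin_intervals()] (kept days).
#' @param policy `"present-only"` (default) ranks among the cows actually
#'   present in the interval, so ranks run 1..n_present; `"complete-only"`
#'   drops intervals where any member of the herd is missing. Intervals with
#'   fewer than 2 cows are always skipped.
#' @return Tibble with `day`, `interval_index`, `cow_id`,
#'   `median_distance_m`, `rank`, `n_present`. The attribute
#'   `skipped_intervals` is a tibble of dropped (day, interval_index) cells
#'   with the reason.
#' @export
interval_ranks <- function(intervals, policy = c("present-only", "complete-only")) {
  policy <- match.arg(policy)
  herd_size <- dplyr::n_distinct(intervals$cow_id)
  key <- factor(paste(intervals$day, intervals$interval_index),
                levels = unique(paste(intervals$day, intervals$interval_index)))
  groups <- split(seq_len(nrow(intervals)), key)

  skipped <- list()
  out <- vector("list", length(groups))
  for (i in seq_along(groups)) {
    g <- groups[[i]]
    n <- length(g)
    if (n < 2 || (policy == "complete-only" && n < herd_size)) {
      skipped[[length(skipped) + 1]] <- tibble::tibble(
        day = intervals$day[g[1]], interval_index = intervals$interval_index[g[1]],
        n_present = n,
        reason = if (n < 2) "fewer than 2 cows" else "herd incomplete")
      next
    }
    if (anyDuplicated(intervals$cow_id[g])) stop("duplicate cow_id within interval")
    d <- haversine_matrix(intervals$lat_med[g], intervals$lon_med[g])
    # median of each row's off-diagonal entries
    med <- vapply(seq_len(n), function(j) stats::median(d[j, -j]), numeric(1))
    out[[i]] <- tibble::tibble(
      day = intervals$day[g[1]], interval_index = intervals$interval_index[g[1]],
      cow_id = intervals$cow_id[g], median_distance_m = med,
      rank = rank(med, ties.method = "average"), n_present = n)
  }
  res <- dplyr::bind_rows(out)
  attr(res, "skipped_intervals") <- dplyr::bind_rows(skipped)
  res
}

#' Daily median rank per cow
#'
#' Collapses a cow's interval ranks within each day to their median: one
#' value per cow per day, low meaning persistently central in the herd.
#'
#' @param ranks Tibble from [interval_ranks()].
#' @return Tibble with `cow_id`, `day`, `median_rank`, `n_intervals_used`.
#'   Cows absent for a whole day simply have no row for that day.
#' @export
daily_median_ranks <- function(ranks) {
  ranks |>
    dplyr::group_by(.data$cow_id, .data$day) |>
    dplyr::summarise(
      median_rank = stats::median(.data$rank),
      n_intervals_used = dplyr::n(),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$cow_id, .data$day)
}

#' Cumulative rank curves
#'
#' The running sum of each cow's daily median ranks over the ordered study
#' days. A persistently central cow accumulates slowly; the final values
#' spread the herd along a rough cohesion hierarchy.
#'
#' Days on which a cow has no daily rank are carried forward: the curve does
#' not advance and the gap is flagged, rather than imputing a rank the data
#' do not support.
#'
#' @param daily Tibble from [daily_median_ranks()].
#' @param days Optional vector of study days defining the grid; defaults to
#'   all days present in `daily`.
#' @return Tibble with `cow_id`, `day`, `median_rank` (NA on gap days),
#'   `cumulative`, `gap` (logical).
#' @export
cumulative_curves <- function(daily, days = NULL) {
  if (is.null(days)) days <- sort(unique(daily$day))
  full <- tidyr::expand_grid(cow_id = unique(daily$cow_id), day = days) |>
    dplyr::left_join(daily, by = c("cow_id", "day")) |>
    dplyr::arrange(.data$cow_id, .data$day) |>
    dplyr::group_by(.data$cow_id) |>
    dplyr::mutate(
      gap = is.na(.data$median_rank),
      cumulative = cumsum(tidyr::replace_na(.data$median_rank, 0))
    ) |>
    dplyr::ungroup() |>
    dplyr::select("cow_id", "day", "median_rank", "cumulative", "gap")
  n_gap <- sum(full$gap)
  if (n_gap > 0) {
    warning(n_gap, " cow-day gap(s) carried forward in cumulative curves")
  }
  full
}

#' Final cumulative rank per cow
#'
#' @param curves Tibble from [cumulative_curves()].
#' @return Tibble with `cow_id` and `cumulative_final`, sorted ascending
#'   (most central cow first).
#' @export
cumulative_finals <- function(curves) {
  curves |>
    dplyr::group_by(.data$cow_id) |>
    dplyr::summarise(cumulative_final = .data$cumulative[which.max(as.numeric(.data$day))],
                     .groups = "drop") |>
    dplyr::arrange(.data$cumulative_final)
}
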