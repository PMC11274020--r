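# Distance-randomization null: does the observed rank structure exceed what
# GPS inaccuracy alone would produce?

#' Randomize median neighbour distances within each interval
#'
#' The null model for GPS inaccuracy: within every 15-min interval the vector
#' of per-cow median neighbour distances is shuffled by a uniform random
#' permutation. This destroys the cow-distance association (any cow is
#' equally likely to receive any rank) while preserving each interval's
#' distance multiset exactly. Ranks are recomputed from the permuted
#' distances.
#'
#' @param ranks Tibble from [interval_ranks()] (needs `day`,
#'   `interval_index`, `cow_id`, `median_distance_m`).
#' @param seed Optional integer seed; with a fixed seed the output is
#'   reproducible.
#' @return A tibble of the same shape with permuted `median_distance_m` and
#'   recomputed `rank`.
#' @export
randomize_distances <- function(ranks, seed = NULL) {
  if (!is.null(seed)) withr::local_seed(seed)
  grp <- paste(ranks$day, ranks$interval_index)
  grp <- factor(grp, levels = unique(grp))
  # shuffle within group: ave() with sample() over within-group indices
  idx <- stats::ave(seq_len(nrow(ranks)), grp,
                    FUN = function(i) if (length(i) > 1) sample(i) else i)
  out <- ranks
  out$median_distance_m <- ranks$median_distance_m[idx]
  out$rank <- stats::ave(out$median_distance_m, grp,
                         FUN = function(x) rank(x, ties.method = "average"))
  out
}

#' Jitter interval positions with isotropic GPS noise
#'
#' The physically motivated alternative null: adds independent Gaussian
#' displacement of standard deviation `sd_m` metres per axis to every
#' interval position, converted to degrees at each row's latitude. Collar
#' GNSS fixes are accurate to roughly 3.5-10 m, so `sd_m` in that range
#' emulates pure measurement error.
#'
#' @param positions Tibble from [bin_intervals()].
#' @param sd_m Noise standard deviation per axis, metres (> 0).
#' @param seed Optional integer seed.
#' @return `positions` with perturbed `lat_med`, `lon_med`.
#' @export
jitter_positions <- function(positions, sd_m, seed = NULL) {
  if (sd_m < 0) stop("sd_m must be >= 0")
  if (!is.null(seed)) withr::local_seed(seed)
  n <- nrow(positions)
  m_per_deg <- EARTH_RADIUS_M * pi / 180
  positions |>
    dplyr::mutate(
      lat_med = .data$lat_med + stats::rnorm(n, 0, sd_m) / m_per_deg,
      lon_med = .data$lon_med +
        stats::rnorm(n, 0, sd_m) / (m_per_deg * cos(.data$lat_med * pi / 180))
    )
}

#' Run replicates of the distance-randomization null
#'
#' Each replicate permutes the per-interval distances
#' ([randomize_distances()]), then re-runs the downstream pipeline: daily
#' median ranks and cumulative curves. Replicate k uses seed
#' `base_seed + k`, recorded in the output.
#'
#' @param ranks Tibble from [interval_ranks()].
#' @param n_reps Number of replicates (the reference design uses 10).
#' @param base_seed Integer; replicate seeds are derived from it.
#' @return A list of replicates, each a list with `replicate_id`, `seed`,
#'   `daily_ranks` (tibble), and `cumulative_final` (tibble from
#'   [cumulative_finals()]).
#' @export
run_null_replicates <- function(ranks, n_reps = 10, base_seed = 1) {
  stopifnot(n_reps >= 1)
  lapply(seq_len(n_reps), function(k) {
    seed_k <- as.integer(base_seed + k)
    randomized <- randomize_distances(ranks, seed = seed_k)
    daily <- daily_median_ranks(randomized)
    finals <- cumulative_finals(suppressWarnings(cumulative_curves(daily)))
    list(replicate_id = k, seed = seed_k, daily_ranks = daily,
         cumulative_final = finals)
  })
}

#' Range of final cumulative values over null replicates
#'
#' @param replicates List from [run_null_replicates()].
#' @return Named numeric vector `c(min = , max = )` over all cows and all
#'   replicates.
#' @export
cumulative_range <- function(replicates) {
  finals <- unlist(lapply(replicates, function(r) r$cumulative_final$cumulative_final))
  c(min = min(finals), max = max(finals))
}

#' Mann-Whitney U test (two-sided)
#'
#' Exact p by enumeration when the combined sample size is at most
#' `exact_threshold` and there are no ties; otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param a,b Non-empty numeric samples.
#' @param exact_threshold Combined-n cutoff for the exact distribution
#'   (default 20).
#' @return A list with `U` (statistic for `a`) and `p` (two-sided).
#' @export
mwu_test <- function(a, b, exact_threshold = 20) {
  if (length(a) == 0 || length(b) == 0) stop("samples must be non-empty")
  use_exact <- (length(a) + length(b)) <= exact_threshold &&
    !anyDuplicated(c(a, b))
  res <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE)
  )
  p <- res$p.value
  # a fully tied pooled sample degenerates the normal approximation (sd = 0);
  # there is then no evidence of any difference
  if (is.na(p)) p <- 1
  list(U = unname(res$statistic), p = p)
}

mwu_matrix <- function(daily_by_cow) {
  cows <- names(daily_by_cow)
  n <- length(cows)
  p <- u <- matrix(NA_real_, n, n, dimnames = list(cows, cows))
  diag(p) <- 1
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      r <- mwu_test(daily_by_cow[[i]], daily_by_cow[[j]])
      p[i, j] <- p[j, i] <- r$p
      u[i, j] <- r$U
      u[j, i] <- length(daily_by_cow[[i]]) * length(daily_by_cow[[j]]) - r$U
    }
  }
  list(labels = cows, u = u, p = p)
}

split_daily <- function(daily) {
  split(daily$median_rank, daily$cow_id)
}

#' Pairwise Mann-Whitney U matrices: original vs randomized
#'
#' Builds the three families of comparisons used to audit GPS accuracy:
#' cow-vs-cow tests on the original daily ranks, cow-vs-cow tests within
#' each null replicate, and each cow's original daily ranks against its own
#' randomized daily ranks per replicate. Real spatial structure shows up as
#' many significant cow-vs-cow cells in the original but few in the
#' randomized data.
#'
#' @param original_daily Tibble from [daily_median_ranks()] on the original
#'   data.
#' @param replicates List from [run_null_replicates()].
#' @param alpha Significance threshold for the summary counts (default
#'   0.05). P-values are reported uncorrected; `holm = TRUE` adds a
#'   Holm-adjusted copy of each p matrix.
#' @param holm Add Holm-adjusted matrices (default `FALSE`).
#' @return A list with `original` (labels/u/p), `replicate` (one per
#'   replicate), `orig_vs_randomized` (cow x replicate matrix of p-values),
#'   and `summary`: fractions of off-diagonal p < alpha per family.
#' @export
build_mwu_matrices <- function(original_daily, replicates, alpha = 0.05, holm = FALSE) {
  orig <- mwu_matrix(split_daily(original_daily))
  reps <- lapply(replicates, function(r) mwu_matrix(split_daily(r$daily_ranks)))

  orig_split <- split_daily(original_daily)
  cows <- names(orig_split)
  ovr <- matrix(NA_real_, length(cows), length(replicates),
                dimnames = list(cows, paste0("rep", seq_along(replicates))))
  for (k in seq_along(replicates)) {
    rep_split <- split_daily(replicates[[k]]$daily_ranks)
    for (cw in cows) {
      ovr[cw, k] <- mwu_test(orig_split[[cw]], rep_split[[cw]])$p
    }
  }

  off <- function(p) p[upper.tri(p)]
  summary <- list(
    frac_sig_original = mean(off(orig$p) < alpha),
    frac_sig_randomized = mean(vapply(reps, function(r) mean(off(r$p) < alpha),
                                      numeric(1))),
    frac_sig_orig_vs_randomized = mean(ovr < alpha),
    alpha = alpha
  )
  if (holm) {
    adjust <- function(m) {
      adj <- m
      adj[upper.tri(adj)] <- stats::p.adjust(m[upper.tri(m)], method = "holm")
      adj[lower.tri(adj)] <- t(adj)[lower.tri(adj)]
      adj
    }
    orig$p_holm <- adjust(orig$p)
    reps <- lapply(reps, function(r) { r$p_holm <- adjust(r$p); r })
  }
  list(original = orig, replicate = reps, orig_vs_randomized = ovr,
       summary = summary)
}
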