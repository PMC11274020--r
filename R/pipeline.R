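# One-command orchestration: ingest -> ranking -> statistics -> null model,
# with a structured report bundle on disk.

#' Run the full herd spatial-rank pipeline
#'
#' Reads a collar message log and collar map, bins positions into 15-min
#' intervals, excludes incompletely registered days, computes interval and
#' daily ranks, cumulative curves, the rank-distribution summary, Kendall's
#' W, boxplot summaries, and the distance-randomization null with its
#' Mann-Whitney U matrices. All outputs are written as tidy CSV/JSON under
#' `out_dir`, together with a run manifest recording configuration, seeds,
#' record counts, excluded days, and a content hash per file.
#'
#' @param messages Path to (or tibble of) the message log; see
#'   [read_message_log()].
#' @param collars Path to (or tibble of) the collar map; see
#'   [read_collar_map()].
#' @param out_dir Output directory (created if needed).
#' @param start,end Optional date window (inclusive) to restrict the
#'   analysis to.
#' @param required_cows Day-exclusion threshold; default the full herd.
#' @param policy Ranking policy, `"present-only"` or `"complete-only"`.
#' @param null_reps Null replicates (default 10); 0 skips the null stage.
#' @param seed Seed for the null randomization.
#' @param strict Strict parsing (see [read_message_log()]).
#' @param verbose Log stage progress with record counts.
#' @return Invisibly, the in-memory bundle: a list with `intervals`,
#'   `day_filter`, `interval_ranks`, `daily_ranks`, `curves`, `finals`,
#'   `density_summary`, `boxplots`, `concordance`, `null` (replicates,
#'   range, W per replicate, MWU summary) and `manifest`.
#' @export
run_pipeline <- function(messages, collars, out_dir,
                         start = NULL, end = NULL,
                         required_cows = NULL,
                         policy = c("present-only", "complete-only"),
                         null_reps = 10, seed = 1,
                         strict = TRUE, verbose = TRUE) {
  policy <- match.arg(policy)
  say <- function(...) if (verbose) message("[herdrank] ", sprintf(...))

  records <- if (is.data.frame(messages)) messages else read_message_log(messages, strict = strict)
  map <- if (is.data.frame(collars)) collars else read_collar_map(collars)
  say("ingest: %d message records, %d collar-map entries", nrow(records), nrow(map))

  if (!"cow_id" %in% names(records)) {
    records <- apply_collar_map(records, map, strict = strict)
  }
  if (!is.null(start)) records <- dplyr::filter(records, as.Date(.data$timestamp, tz = "UTC") >= as.Date(start))
  if (!is.null(end)) records <- dplyr::filter(records, as.Date(.data$timestamp, tz = "UTC") <= as.Date(end))

  intervals <- bin_intervals(records)
  say("binning: %d interval positions from %d records", nrow(intervals), nrow(records))

  filt <- exclude_incomplete_days(intervals, required_cows = required_cows)
  say("day filter: %d days kept, %d excluded", length(filt$report$kept_days),
      nrow(filt$report$excluded_days))

  iranks <- interval_ranks(filt$intervals, policy = policy)
  daily <- daily_median_ranks(iranks)
  curves <- suppressWarnings(cumulative_curves(daily))
  finals <- cumulative_finals(curves)
  say("ranking: %d interval-rank rows, %d cow-days", nrow(iranks), nrow(daily))

  dens <- density_summary(daily)
  boxes <- daily |>
    dplyr::group_by(.data$cow_id) |>
    dplyr::summarise(s = list(boxplot_summary(.data$median_rank)), .groups = "drop") |>
    tidyr::unnest_wider("s") |>
    dplyr::mutate(outliers = vapply(.data$outliers, function(o) paste(o, collapse = ";"),
                                    character(1)))

  rank_mat <- daily_rank_matrix(daily)
  if (anyNA(rank_mat)) {
    # gap policy for W: a missing cow-day would make days incomparable, so
    # impute the within-day midrank of the remaining mass (herd median)
    for (r in seq_len(nrow(rank_mat))) {
      miss <- is.na(rank_mat[r, ])
      if (any(miss)) rank_mat[r, miss] <- stats::median(rank_mat[r, !miss])
    }
    say("concordance: imputed %d missing cow-day cells at the day median",
        sum(is.na(daily_rank_matrix(daily))))
  }
  conc <- kendalls_w(rank_mat)
  conc_nt <- kendalls_w(rank_mat, ties_correction = FALSE)
  say("concordance: W = %.3f (p = %.3g)", conc$W, conc$p)

  null <- NULL
  if (null_reps > 0) {
    reps <- run_null_replicates(iranks, n_reps = null_reps, base_seed = seed)
    rng <- cumulative_range(reps)
    w_per_rep <- vapply(reps, function(r) {
      m <- daily_rank_matrix(r$daily_ranks)
      if (anyNA(m)) for (i in seq_len(nrow(m))) m[i, is.na(m[i, ])] <- stats::median(m[i, ], na.rm = TRUE)
      kendalls_w(m)$W
    }, numeric(1))
    mwu <- build_mwu_matrices(daily, reps)
    null <- list(replicates = reps, range = rng, W = w_per_rep, mwu = mwu)
    say("null: cumulative range %.2f-%.2f over %d replicates", rng[1], rng[2], null_reps)
  }

  bundle <- list(intervals = filt$intervals, day_filter = filt$report,
                 interval_ranks = iranks, daily_ranks = daily, curves = curves,
                 finals = finals, density_summary = dens, boxplots = boxes,
                 concordance = conc, concordance_no_ties_corr = conc_nt,
                 null = null,
                 config = list(policy = policy, required_cows = required_cows,
                               null_reps = null_reps, seed = seed,
                               n_records = nrow(records)))
  bundle$manifest <- write_report(bundle, out_dir)
  invisible(bundle)
}

#' Write a pipeline report bundle to disk
#'
#' @param bundle List as assembled by [run_pipeline()].
#' @param out_dir Output directory.
#' @return The manifest (list), also written as `manifest.json`.
#' @export
write_report <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir)) stop("cannot create output directory ", out_dir)
  files <- character(0)
  wcsv <- function(x, name) {
    path <- file.path(out_dir, name)
    readr::write_csv(x, path)
    files <<- c(files, name)
  }
  wjson <- function(x, name) {
    path <- file.path(out_dir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
    files <<- c(files, name)
  }

  wcsv(bundle$interval_ranks, "interval_ranks.csv")
  wcsv(bundle$daily_ranks, "daily_ranks.csv")
  wcsv(bundle$curves, "cumulative.csv")
  wcsv(bundle$finals, "cumulative_finals.csv")
  wcsv(bundle$density_summary, "density_summary.csv")
  wcsv(bundle$boxplots, "boxplot_summary.csv")
  wjson(list(kept_days = as.character(bundle$day_filter$kept_days),
             excluded_days = as.character(bundle$day_filter$excluded_days$day)),
        "day_filter.json")
  wjson(list(ties_corrected = unclass(bundle$concordance),
             uncorrected = unclass(bundle$concordance_no_ties_corr)),
        "concordance.json")

  if (!is.null(bundle$null)) {
    wmat <- function(m, name) wcsv(tibble::as_tibble(m, rownames = "cow_id"), name)
    wmat(bundle$null$mwu$original$p, "mwu_original.csv")
    for (k in seq_along(bundle$null$mwu$replicate)) {
      wmat(bundle$null$mwu$replicate[[k]]$p, sprintf("mwu_rep_%02d.csv", k))
    }
    wmat(bundle$null$mwu$orig_vs_randomized, "mwu_orig_vs_rep.csv")
    wjson(list(cumulative_range = as.list(bundle$null$range),
               W_per_replicate = bundle$null$W,
               seeds = vapply(bundle$null$replicates, `[[`, integer(1), "seed"),
               mwu_summary = bundle$null$mwu$summary),
          "null_summary.json")
  }

  manifest <- list(
    created = format(Sys.time(), tz = "UTC", usetz = TRUE),
    config = bundle$config,
    n_interval_positions = nrow(bundle$intervals),
    n_days_kept = length(bundle$day_filter$kept_days),
    excluded_days = as.character(bundle$day_filter$excluded_days$day),
    files = lapply(stats::setNames(files, files), function(f) {
      list(md5 = unname(tools::md5sum(file.path(out_dir, f))))
    })
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest
}
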