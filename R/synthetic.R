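# Synthetic herd-movement generator: a cohesive herd with a planted
# proximity hierarchy, emitting the same collar message-log dialect the
# ingest module reads.

#' Simulation configuration for a synthetic herd
#'
#' The generator emulates the data-generating setting of a virtually fenced
#' herd: a cohesive group drifting through a paddock, each animal holding a
#' characteristic spread around the herd centroid, reported by asynchronous
#' collars with GPS noise and message loss.
#'
#' The centroid follows a correlated random walk (lognormal step lengths,
#' wrapped-normal turning angles) with mild attraction to the paddock
#' origin. Cow i's displacement from the centroid is a first-order
#' autoregressive process per axis with persistence `phi` and stationary
#' standard deviation `sigma_m[i]`: small sigma means a cow that stays near
#' the herd centre, so `sigma_m` *is* the planted cohesion hierarchy.
#'
#' @param n_cows Herd size (default 17).
#' @param n_days Study days (default 45).
#' @param intervals_per_day Poll intervals per day (default 96, i.e. 15 min).
#' @param sigma_m Per-cow stationary spread around the centroid, metres;
#'   default evenly spaced 10-150 m.
#' @param phi AR(1) persistence of the displacement, in `[0, 1)`
#'   (default 0.9).
#' @param step_meanlog,step_sdlog Lognormal parameters of the centroid step
#'   length per 15 min, metres (defaults give a median step of ~20 m).
#' @param turn_sd Standard deviation of the wrapped-normal turning angle,
#'   radians (default 0.8).
#' @param home_pull Fractional per-step attraction of the centroid to the
#'   origin (default 0.02), keeping the herd inside a paddock-sized range.
#' @param gps_noise_sd_m GPS noise per axis, metres (default 2.5, consistent
#'   with collar GNSS accuracy of 3.5-10 m as a ~2 sigma circle).
#' @param dropout_prob Probability a poll is lost to poor coverage
#'   (default 0.05).
#' @param outage_days List of `list(day = <int>, cows = <ids or indices>)`
#'   silencing whole cow-days (emulating collars down for a day).
#' @param event_rate Rate at which extra warning/zap messages are emitted as
#'   additional position sources (default 0.01 per cow-interval).
#' @param origin `c(lat, lon)` of the paddock centre (default 55.42, 8.40).
#' @param start_date First study day (default `"2023-08-15"`).
#' @param seed Integer seed driving every stochastic draw.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_cows = 17, n_days = 45, intervals_per_day = 96,
                       sigma_m = seq(10, 150, length.out = n_cows),
                       phi = 0.9,
                       step_meanlog = log(20), step_sdlog = 0.6,
                       turn_sd = 0.8, home_pull = 0.02,
                       gps_noise_sd_m = 2.5, dropout_prob = 0.05,
                       outage_days = list(), event_rate = 0.01,
                       origin = c(55.42, 8.40),
                       start_date = "2023-08-15", seed = 1) {
  stopifnot(n_cows >= 2, length(sigma_m) == n_cows, all(sigma_m > 0),
            phi >= 0, phi < 1, dropout_prob >= 0, dropout_prob <= 1,
            gps_noise_sd_m >= 0)
  structure(
    list(n_cows = n_cows, n_days = n_days, intervals_per_day = intervals_per_day,
         sigma_m = sigma_m, phi = phi, step_meanlog = step_meanlog,
         step_sdlog = step_sdlog, turn_sd = turn_sd, home_pull = home_pull,
         gps_noise_sd_m = gps_noise_sd_m, dropout_prob = dropout_prob,
         outage_days = outage_days, event_rate = event_rate, origin = origin,
         start_date = as.Date(start_date), seed = as.integer(seed),
         cow_ids = sprintf("Cow%02d", seq_len(n_cows)),
         serials = sprintf("SN%04d", 1000 + seq_len(n_cows))),
    class = "sim_config")
}

#' Planted cohesion hierarchy of a simulation
#'
#' @param config A [sim_config()].
#' @return Character vector of cow IDs ordered by `sigma_m` ascending: the
#'   most cohesive (centre-holding) cow first. This is the ground truth the
#'   cumulative-rank pipeline should recover.
#' @export
planted_order <- function(config) {
  config$cow_ids[order(config$sigma_m)]
}

#' Simulate herd tracks at the poll grid
#'
#' @param config A [sim_config()].
#' @return A list with `times` (vector of POSIXct interval starts), `lat`,
#'   `lon`: steps x cows matrices of true positions, and `config`.
#' @export
simulate_tracks <- function(config) {
  withr::local_seed(config$seed)
  n_steps <- config$n_days * config$intervals_per_day
  n <- config$n_cows
  m_per_deg <- EARTH_RADIUS_M * pi / 180

  # centroid: correlated random walk with mild home attraction, metres E/N
  steps <- stats::rlnorm(n_steps, config$step_meanlog, config$step_sdlog)
  turns <- stats::rnorm(n_steps, 0, config$turn_sd)
  heading <- cumsum(c(stats::runif(1, 0, 2 * pi), turns[-1])) %% (2 * pi)
  cx <- cy <- numeric(n_steps)
  for (t in 2:n_steps) {
    cx[t] <- cx[t - 1] * (1 - config$home_pull) + steps[t] * cos(heading[t])
    cy[t] <- cy[t - 1] * (1 - config$home_pull) + steps[t] * sin(heading[t])
  }

  # per-cow AR(1) displacement, stationary sd sigma_i per axis
  dx <- dy <- matrix(0, n_steps, n)
  innov_sd <- config$sigma_m * sqrt(1 - config$phi^2)
  dx[1, ] <- stats::rnorm(n, 0, config$sigma_m)
  dy[1, ] <- stats::rnorm(n, 0, config$sigma_m)
  for (t in 2:n_steps) {
    dx[t, ] <- config$phi * dx[t - 1, ] + stats::rnorm(n, 0, innov_sd)
    dy[t, ] <- config$phi * dy[t - 1, ] + stats::rnorm(n, 0, innov_sd)
  }

  x <- sweep(dx, 1, cx, "+")
  y <- sweep(dy, 1, cy, "+")
  lat <- config$origin[1] + y / m_per_deg
  lon <- config$origin[2] + x / (m_per_deg * cos(config$origin[1] * pi / 180))
  colnames(lat) <- colnames(lon) <- config$cow_ids

  t0 <- as.POSIXct(paste(config$start_date, "00:00:00"), tz = "UTC")
  times <- t0 + (seq_len(n_steps) - 1) * INTERVAL_SEC
  list(times = times, lat = lat, lon = lon, config = config)
}

#' Emit a collar message log from simulated tracks
#'
#' Per cow, one poll per interval at that cow's fixed phase offset (uniform
#' on 0-15 min, so collars are asynchronous as in the field), with isotropic
#' Gaussian GPS noise added. Each poll is independently dropped with
#' `dropout_prob`; `outage_days` silence listed cows for whole days,
#' producing the incomplete days [exclude_incomplete_days()] must catch.
#' Extra warning/zap messages appear at `event_rate` as additional position
#' sources within an interval.
#'
#' @param tracks Output of [simulate_tracks()].
#' @return A message-record tibble in the same dialect [read_message_log()]
#'   returns (`serial`, `timestamp`, `lat`, `lon`, `msg_type`), sorted by
#'   time.
#' @export
emit_message_log <- function(tracks) {
  config <- tracks$config
  withr::local_seed(config$seed + 1L)
  n <- config$n_cows
  n_steps <- length(tracks$times)
  m_per_deg <- EARTH_RADIUS_M * pi / 180
  phase <- stats::runif(n, 0, INTERVAL_SEC)

  day_index <- rep(seq_len(config$n_days), each = config$intervals_per_day)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    keep <- stats::runif(n_steps) >= config$dropout_prob
    for (o in config$outage_days) {
      cows <- o$cows
      if (is.numeric(cows)) cows <- config$cow_ids[cows]
      if (config$cow_ids[i] %in% cows) keep[day_index == o$day] <- FALSE
    }
    n_extra <- stats::rbinom(1, n_steps, config$event_rate)
    extra_steps <- if (n_extra > 0) sample.int(n_steps, n_extra) else integer(0)
    extra_steps <- extra_steps[keep[extra_steps]]

    idx <- c(which(keep), extra_steps)
    type <- c(rep("poll", sum(keep)),
              sample(c("warning", "zap"), length(extra_steps),
                     replace = TRUE, prob = c(0.8, 0.2)))
    offset <- c(rep(phase[i], sum(keep)),
                stats::runif(length(extra_steps), 0, INTERVAL_SEC))
    m <- length(idx)
    if (m == 0) next
    lat0 <- tracks$lat[idx, i]
    out[[i]] <- tibble::tibble(
      serial = config$serials[i],
      timestamp = tracks$times[idx] + offset,
      lat = lat0 + stats::rnorm(m, 0, config$gps_noise_sd_m) / m_per_deg,
      lon = tracks$lon[idx, i] +
        stats::rnorm(m, 0, config$gps_noise_sd_m) /
          (m_per_deg * cos(config$origin[1] * pi / 180)),
      msg_type = type
    )
  }
  if (all(vapply(out, is.null, logical(1)))) {
    return(tibble::tibble(serial = character(), timestamp = as.POSIXct(character(), tz = "UTC"),
                          lat = numeric(), lon = numeric(), msg_type = character()))
  }
  dplyr::bind_rows(out) |> dplyr::arrange(.data$timestamp, .data$serial)
}

#' Simulate a complete message log in one call
#'
#' Convenience wrapper: [simulate_tracks()] then [emit_message_log()].
#'
#' @param config A [sim_config()].
#' @return A list with `log` (message tibble), `collar_map` (one serial per
#'   cow, valid over the whole window), `hierarchy`
#'   ([planted_order()] result) and `config`.
#' @export
simulate_message_log <- function(config) {
  tracks <- simulate_tracks(config)
  log <- emit_message_log(tracks)
  map <- tibble::tibble(
    serial = config$serials, cow_id = config$cow_ids,
    valid_from = config$start_date,
    valid_to = config$start_date + config$n_days
  )
  list(log = log, collar_map = map, hierarchy = planted_order(config),
       config = config)
}
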