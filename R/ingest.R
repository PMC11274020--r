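# Ingest: collar message logs -> aligned 15-min interval positions.

MSG_TYPES <- c("poll", "warning", "zap")
INTERVAL_SEC <- 900L
INTERVALS_PER_DAY <- 96L

#' Read a collar message log
#'
#' Parses a delimited message log with header
#' `serial,timestamp,lat,lon,msg_type`. Each row is one collar transmission:
#' a routine position poll, an auditory border warning, or an electric-pulse
#' ("zap") event. Warning and zap rows carry GPS fixes and are retained as
#' position sources alongside polls.
#'
#' @param file Path, connection or literal CSV text (anything
#'   [readr::read_csv()] accepts).
#' @param strict If `TRUE` (default) any malformed row aborts with its line
#'   number; if `FALSE` malformed rows are dropped, counted, and reported in
#'   the `rejected` attribute of the result.
#'
#' @return A tibble with columns `serial` (character), `timestamp` (POSIXct,
#'   UTC), `lat`, `lon` (degrees, WGS84) and `msg_type`
#'   (`"poll"`, `"warning"` or `"zap"`). In lenient mode the attribute
#'   `rejected` holds a tibble of dropped rows (`line`, `reason`).
#' @export
read_message_log <- function(file, strict = TRUE) {
  raw <- readr::read_csv(file, col_types = readr::cols(.default = readr::col_character()))
  required <- c("serial", "timestamp", "lat", "lon", "msg_type")
  missing_cols <- setdiff(required, names(raw))
  if (length(missing_cols) > 0) {
    stop("message log is missing column(s): ", paste(missing_cols, collapse = ", "))
  }

  ts <- suppressWarnings(readr::parse_datetime(raw$timestamp))
  attr(ts, "tzone") <- "UTC"
  lat <- suppressWarnings(as.numeric(raw$lat))
  lon <- suppressWarnings(as.numeric(raw$lon))

  reason <- rep(NA_character_, nrow(raw))
  reason[is.na(ts)] <- "unparseable timestamp"
  reason[is.na(lat) | lat < -90 | lat > 90] <- "latitude outside [-90, 90]"
  reason[is.na(lon) | lon < -180 | lon > 180] <- "longitude outside [-180, 180]"
  reason[!(raw$msg_type %in% MSG_TYPES)] <-
    paste0("msg_type not one of {", paste(MSG_TYPES, collapse = ", "), "}")
  bad <- which(!is.na(reason))

  if (length(bad) > 0 && strict) {
    # +1 for the header line so the number matches the file as seen in an editor
    stop("malformed message row(s) at line(s) ",
         paste(utils::head(bad + 1L, 10), collapse = ", "),
         ": ", reason[bad[1]])
  }

  keep <- setdiff(seq_len(nrow(raw)), bad)
  out <- tibble::tibble(
    serial = raw$serial[keep],
    timestamp = ts[keep],
    lat = lat[keep],
    lon = lon[keep],
    msg_type = raw$msg_type[keep]
  )
  attr(out, "rejected") <- tibble::tibble(line = bad + 1L, reason = reason[bad])
  out
}

#' Read a collar-serial to cow-ID mapping
#'
#' A cow may own more than one serial (a collar swapped mid-study) provided
#' the validity windows do not overlap; every serial maps to exactly one cow.
#'
#' @param file CSV with header `serial,cow_id,valid_from,valid_to`
#'   (dates inclusive).
#' @return A tibble with those four columns (`valid_from`/`valid_to` as Date).
#' @export
read_collar_map <- function(file) {
  map <- readr::read_csv(file, col_types = readr::cols(
    serial = readr::col_character(),
    cow_id = readr::col_character(),
    valid_from = readr::col_date(),
    valid_to = readr::col_date()
  ))
  validate_collar_map(map)
  map
}

validate_collar_map <- function(map) {
  dup <- map |>
    dplyr::count(.data$serial, .data$cow_id) |>
    dplyr::count(.data$serial) |>
    dplyr::filter(.data$n > 1)
  if (nrow(dup) > 0) {
    stop("serial(s) mapped to more than one cow: ", paste(dup$serial, collapse = ", "))
  }
  if (any(map$valid_from > map$valid_to)) stop("collar map has valid_from > valid_to")
  # overlapping validity windows for the same cow are a configuration error
  by_cow <- split(map, map$cow_id)
  for (m in by_cow) {
    if (nrow(m) < 2) next
    m <- m[order(m$valid_from), ]
    if (any(m$valid_from[-1] <= m$valid_to[-nrow(m)])) {
      stop("overlapping collar validity windows for cow ", m$cow_id[1])
    }
  }
  invisible(map)
}

#' Attach cow identities to message records
#'
#' Joins records to the collar map by serial and validity window, so that two
#' serials worn by the same animal in adjacent windows resolve to a single
#' `cow_id` stream.
#'
#' @param records Tibble from [read_message_log()].
#' @param map Tibble from [read_collar_map()].
#' @param strict If `TRUE` (default) an unmapped serial, or a record dated
#'   outside every validity window of its serial, is an error; if `FALSE`
#'   such records are dropped with a warning.
#' @return `records` with a `cow_id` column; record count preserved in
#'   strict mode.
#' @export
apply_collar_map <- function(records, map, strict = TRUE) {
  validate_collar_map(map)
  joined <- records |>
    dplyr::mutate(.row = dplyr::row_number(),
                  .date = as.Date(.data$timestamp, tz = "UTC")) |>
    dplyr::left_join(map, by = "serial", relationship = "many-to-many") |>
    dplyr::mutate(.valid = !is.na(.data$cow_id) &
                    .data$.date >= .data$valid_from & .data$.date <= .data$valid_to)

  matched <- joined |> dplyr::filter(.data$.valid)
  unmatched <- joined |>
    dplyr::filter(!.data$.row %in% matched$.row) |>
    dplyr::distinct(.data$.row, .keep_all = TRUE)

  if (nrow(unmatched) > 0) {
    unmapped <- setdiff(unique(unmatched$serial), map$serial)
    outside <- unmatched |> dplyr::filter(.data$serial %in% map$serial)
    msg <- c(
      if (length(unmapped) > 0) paste0("unmapped serial(s): ", paste(unmapped, collapse = ", ")),
      if (nrow(outside) > 0) paste0(
        "record(s) outside all validity windows: ",
        paste(utils::head(paste0(outside$serial, "@", outside$.date), 5), collapse = ", ")
      )
    )
    if (strict) stop(paste(msg, collapse = "; ")) else warning(paste(msg, collapse = "; "))
  }

  matched |>
    dplyr::arrange(.data$.row) |>
    dplyr::select("serial", "cow_id", "timestamp", "lat", "lon", "msg_type")
}

#' Bin positioned messages into 15-minute UTC intervals
#'
#' Collars report asynchronously, so positions are aligned onto a common grid
#' of 96 quarter-hour intervals per UTC day, the first labelled
#' 00:00-00:15. Intervals are half-open `[t, t + 15 min)`: a fix at exactly
#' 00:15:00 belongs to interval 1, not 0. When a cow has several fixes in one
#' interval (polls pooled with warnings and zaps), the coordinate-wise median
#' of latitude and longitude is stored.
#'
#' @param records Tibble with `cow_id`, `timestamp`, `lat`, `lon`.
#' @return A tibble of interval positions: `cow_id`, `day` (UTC Date),
#'   `interval_index` (0-95), `lat_med`, `lon_med`, `n_messages`.
#' @export
bin_intervals <- function(records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(cow_id = character(), day = as.Date(character()),
                          interval_index = integer(), lat_med = numeric(),
                          lon_med = numeric(), n_messages = integer()))
  }
  stopifnot("cow_id" %in% names(records))
  secs <- as.numeric(records$timestamp) %% 86400
  records |>
    dplyr::mutate(
      day = as.Date(.data$timestamp, tz = "UTC"),
      interval_index = as.integer(floor(secs / INTERVAL_SEC))
    ) |>
    dplyr::group_by(.data$cow_id, .data$day, .data$interval_index) |>
    dplyr::summarise(
      lat_med = stats::median(.data$lat),
      lon_med = stats::median(.data$lon),
      n_messages = dplyr::n(),
      .groups = "drop"
    )
}

#' Exclude days with incomplete herd registration
#'
#' Collars lose power or mobile coverage, leaving whole days on which fewer
#' than the full herd transmitted. Such days are removed before ranking, since
#' ranks on an incompletely registered day are not comparable across the herd.
#'
#' @param intervals Interval-position tibble from [bin_intervals()].
#' @param required_cows Minimum number of distinct cows that must have at
#'   least one interval position for the day to be kept. Defaults to the
#'   number of distinct cows seen anywhere in `intervals` (the full herd).
#' @return A list with `intervals` (rows on kept days only) and `report`, a
#'   list with `kept_days`, and `excluded_days` as a tibble
#'   (`day`, `cows_registered`, `reason`).
#' @export
exclude_incomplete_days <- function(intervals, required_cows = NULL) {
  herd_size <- dplyr::n_distinct(intervals$cow_id)
  if (is.null(required_cows)) required_cows <- herd_size
  if (required_cows > herd_size) {
    stop("required_cows (", required_cows, ") exceeds herd size (", herd_size, ")")
  }
  per_day <- intervals |>
    dplyr::group_by(.data$day) |>
    dplyr::summarise(cows_registered = dplyr::n_distinct(.data$cow_id), .groups = "drop")
  excluded <- per_day |>
    dplyr::filter(.data$cows_registered < required_cows) |>
    dplyr::mutate(reason = paste0("cows_registered < ", required_cows))
  kept <- sort(per_day$day[!per_day$day %in% excluded$day])
  list(
    intervals = dplyr::filter(intervals, .data$day %in% kept),
    report = list(kept_days = kept, excluded_days = excluded)
  )
}
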