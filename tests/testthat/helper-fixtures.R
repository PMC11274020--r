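# Shared fixture builders; everything is generated in code.

# literal CSV log text -> tibble via the package reader
log_csv <- function(rows, header = "serial,timestamp,lat,lon,msg_type") {
  I(paste(c(header, rows), collapse = "\n"))
}

# a compact interval-rank input table: every (day, interval) holds one
# distance per cow (distinct by default), as interval_ranks() would emit
make_rank_input <- function(n_cows = 17, n_days = 45, n_intervals = 96,
                            distances = seq_len(n_cows) * 10) {
  grid <- tidyr::expand_grid(
    day = as.Date("2023-08-15") + seq_len(n_days) - 1,
    interval_index = seq_len(n_intervals) - 1L,
    cow_id = sprintf("Cow%02d", seq_len(n_cows))
  )
  grid$median_distance_m <- rep(distances, times = n_days * n_intervals)
  grid$rank <- stats::ave(grid$median_distance_m,
                          paste(grid$day, grid$interval_index),
                          FUN = function(x) rank(x, ties.method = "average"))
  grid$n_present <- n_cows
  grid
}

# brute-force Kendall's W straight from the defining formula (tie-free),
# independent of the package implementation
w_oracle_tie_free <- function(rank_matrix) {
  m <- nrow(rank_matrix); n <- ncol(rank_matrix)
  R <- colSums(rank_matrix)
  S <- sum((R - mean(R))^2)
  12 * S / (m^2 * (n^3 - n))
}

# exact two-sided Mann-Whitney p by full enumeration of group assignments
mwu_p_enumeration <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a)
  u_of <- function(x, y) sum(outer(x, y, ">")) + 0.5 * sum(outer(x, y, "=="))
  combos <- utils::combn(length(pooled), n_a)
  u_obs <- u_of(a, b)
  u_all <- apply(combos, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  mu <- n_a * (length(pooled) - n_a) / 2
  mean(abs(u_all - mu) >= abs(u_obs - mu))
}
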