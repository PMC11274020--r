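test_that("haversine distance matches the meridian closed form and is symmetric", {
  expect_equal(haversine_m(55, 8, 55, 8), 0)
  # one degree of latitude along a meridian: R * pi / 180
  expect_equal(haversine_m(55, 8, 56, 8), 6371008.8 * pi / 180, tolerance = 1e-9)
  set.seed(42)
  for (i in 1:20) {
    p <- runif(4, -1, 1) * c(80, 170, 80, 170)
    expect_equal(haversine_m(p[1], p[2], p[3], p[4]),
                 haversine_m(p[3], p[4], p[1], p[2]))
  }
  expect_error(haversine_m(95, 0, 0, 0), "out of range")
})

test_that("interval distance matrices are symmetric with zero diagonal", {
  # 3 collinear cows at 0, 100, 300 m along a meridian
  deg_per_m <- 180 / (pi * 6371008.8)
  pos <- tibble::tibble(cow_id = c("a", "b", "c"),
                        lat_med = 55 + c(0, 100, 300) * deg_per_m,
                        lon_med = 8)
  d <- interval_distance_matrix(pos)
  expect_equal(d["a", "b"], 100, tolerance = 1e-6)
  expect_equal(d["a", "c"], 300, tolerance = 1e-6)
  expect_equal(d["b", "c"], 200, tolerance = 1e-6)
  expect_equal(d, t(d))
  expect_equal(unname(diag(d)), rep(0, 3))

  # coincident herd -> all-zero matrix
  same <- tibble::tibble(cow_id = sprintf("c%02d", 1:17), lat_med = 55.42, lon_med = 8.40)
  expect_true(all(interval_distance_matrix(same) == 0))

  set.seed(7)
  rnd <- tibble::tibble(cow_id = sprintf("c%d", 1:8),
                        lat_med = 55.4 + runif(8, 0, 0.01),
                        lon_med = 8.4 + runif(8, 0, 0.01))
  dr <- interval_distance_matrix(rnd)
  expect_equal(dr, t(dr))
  expect_true(all(diag(dr) == 0))
  expect_error(interval_distance_matrix(rnd[1, ]), "at least 2")
})

test_that("median neighbour distance is the median of off-diagonal row entries", {
  d <- matrix(50, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  diag(d) <- 0
  expect_equal(median_neighbour_distance(d, "a"), 50)

  d2 <- matrix(0, 5, 5, dimnames = list(letters[1:5], letters[1:5]))
  d2["a", c("b", "c", "d", "e")] <- 1:4
  d2[c("b", "c", "d", "e"), "a"] <- 1:4
  expect_equal(median_neighbour_distance(d2, "a"), 2.5)

  set.seed(11)
  m <- matrix(runif(17 * 17, 0, 500), 17, 17)
  m <- (m + t(m)) / 2; diag(m) <- 0
  dimnames(m) <- list(sprintf("c%02d", 1:17), sprintf("c%02d", 1:17))
  for (cw in sample(rownames(m), 5)) {
    row <- m[cw, setdiff(colnames(m), cw)]
    expect_equal(median_neighbour_distance(m, cw),
                 sort(row)[8:9] |> mean())   # sort-and-pick oracle, 16 values
  }
  expect_error(median_neighbour_distance(m, "nope"), "not present")
})

test_that("within-interval ranks are ascending with midranks for ties", {
  med <- stats::setNames(seq(10, 170, by = 10), sprintf("c%02d", 1:17))
  r <- rank_within_interval(med)
  expect_equal(r$rank, as.numeric(1:17))
  expect_equal(r$n_present, rep(17L, 17))

  tied <- c(a = 5, b = 5, c = 9)
  rt <- rank_within_interval(tied)
  expect_equal(rt$rank[rt$cow_id %in% c("a", "b")], c(1.5, 1.5))

  # rank-sum conservation across random tie patterns
  set.seed(99)
  for (i in 1:50) {
    n <- sample(2:17, 1)
    v <- stats::setNames(sample(1:5, n, replace = TRUE), paste0("c", 1:n))
    expect_equal(sum(rank_within_interval(v)$rank), n * (n + 1) / 2)
  }
})

test_that("daily median ranks collapse a cow's interval ranks correctly", {
  day <- as.Date("2023-08-15")
  ir <- tibble::tibble(day = day, interval_index = 0:95, cow_id = "Cow01",
                       median_distance_m = 1, rank = 5, n_present = 17)
  expect_equal(daily_median_ranks(ir)$median_rank, 5)
  expect_equal(daily_median_ranks(ir)$n_intervals_used, 96L)

  two <- tibble::tibble(day = day, interval_index = 0:1, cow_id = "Cow01",
                        median_distance_m = 1, rank = c(3, 7), n_present = 17)
  expect_equal(daily_median_ranks(two)$median_rank, 5)

  set.seed(5)
  rnd <- tibble::tibble(day = day, interval_index = 0:30, cow_id = "Cow01",
                        median_distance_m = 1,
                        rank = sample(1:17, 31, replace = TRUE), n_present = 17)
  expect_equal(daily_median_ranks(rnd)$median_rank,
               sort(rnd$rank)[16])   # brute-force median oracle (odd n)
})

test_that("cumulative curves are prefix sums, non-decreasing, gaps carried forward", {
  days <- as.Date("2023-08-15") + 0:44
  daily <- tibble::tibble(cow_id = "Cow01", day = days, median_rank = 9,
                          n_intervals_used = 96L)
  cc <- cumulative_curves(daily)
  expect_equal(cc$cumulative[45], 405)
  expect_equal(cc$cumulative, cumsum(rep(9, 45)))

  one <- tibble::tibble(cow_id = "Cow01", day = days[1], median_rank = 7,
                        n_intervals_used = 1L)
  expect_equal(cumulative_curves(one)$cumulative, 7)

  set.seed(21)
  rnd <- tibble::tibble(cow_id = "Cow01", day = days,
                        median_rank = sample(seq(1, 17, by = 0.5), 45, TRUE),
                        n_intervals_used = 96L)
  cr <- cumulative_curves(rnd)
  expect_equal(dplyr::last(cr$cumulative), sum(rnd$median_rank))
  expect_true(all(diff(cr$cumulative) >= 0))

  gappy <- rnd[-c(10, 20), ]
  expect_warning(cg <- cumulative_curves(gappy, days = days), "gap")
  expect_equal(sum(cg$gap), 2)
  expect_equal(dplyr::last(cg$cumulative), sum(gappy$median_rank))
})

test_that("ranks are invariant to cow relabelling and distance rescaling", {
  cfg <- sim_config(n_cows = 5, n_days = 2, sigma_m = c(10, 30, 60, 90, 120),
                    dropout_prob = 0, event_rate = 0, seed = 13)
  sim <- simulate_message_log(cfg)
  iv <- bin_intervals(apply_collar_map(sim$log, sim$collar_map))
  ir <- interval_ranks(iv)

  # relabelling permutes outputs identically
  perm <- stats::setNames(sprintf("Z%02d", c(3, 1, 5, 2, 4)), sort(unique(iv$cow_id)))
  iv2 <- dplyr::mutate(iv, cow_id = unname(perm[cow_id]))
  ir2 <- interval_ranks(iv2)
  joined <- dplyr::inner_join(
    ir, dplyr::mutate(ir2, cow_id_orig = names(perm)[match(cow_id, perm)]),
    by = c("day", "interval_index", "cow_id" = "cow_id_orig"))
  expect_equal(joined$rank.x, joined$rank.y)

  # scaling all pairwise distances leaves ranks unchanged: spread positions
  # away from the centroid of each interval by a constant factor
  centre <- iv |>
    dplyr::group_by(.data$day, .data$interval_index) |>
    dplyr::mutate(lat_med = 3 * (.data$lat_med - mean(.data$lat_med)) + mean(.data$lat_med),
                  lon_med = 3 * (.data$lon_med - mean(.data$lon_med)) + mean(.data$lon_med)) |>
    dplyr::ungroup()
  ir3 <- interval_ranks(centre)
  expect_equal(ir3$rank, ir$rank)
})

test_that("complete-only policy drops intervals with absent cows", {
  cfg <- sim_config(n_cows = 5, n_days = 2, sigma_m = c(10, 30, 60, 90, 120),
                    dropout_prob = 0.2, event_rate = 0, seed = 17)
  sim <- simulate_message_log(cfg)
  iv <- bin_intervals(apply_collar_map(sim$log, sim$collar_map))
  strictr <- interval_ranks(iv, policy = "complete-only")
  expect_true(all(strictr$n_present == 5))
  presentr <- interval_ranks(iv, policy = "present-only")
  expect_true(any(presentr$n_present < 5))
  expect_true(all(presentr$n_present >= 2))
  skipped <- attr(presentr, "skipped_intervals")
  if (nrow(skipped) > 0) expect_true(all(skipped$n_present < 2))
})
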