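test_that("constants validate their invariants", {
  k <- model_constants()
  expect_s3_class(k, "model_constants")
  expect_error(model_constants(s_min = 2, s_max = 1), "s_min < s_max")
  expect_error(model_constants(t_nest = -1), "t_nest")
  expect_error(model_constants(angle_short = 20, angle_long = 10), "angle")
  expect_error(model_constants(trip_time_threshold = 30), "exceed t_nest")
  expect_error(model_constants(min_trips = 0), "min_trips")
})

test_that("distance band reproduces hand-evaluated values", {
  b600 <- estimate_distance_band(600)
  expect_equal(b600$d_min_m, 499.5)   # (600-45)/2 * 1.8
  expect_equal(b600$d_max_m, 1498.5)  # (600-45)/2 * 5.4
  b345 <- estimate_distance_band(345)
  expect_equal(b345$d_min_m, 270)     # 150 * 1.8
  expect_equal(b345$d_max_m, 810)     # 150 * 5.4
  expect_error(estimate_distance_band(45), "infeasible")
  expect_error(estimate_distance_band(30), "infeasible")
})

test_that("band ratio equals s_max/s_min and grows monotonically with t_min", {
  k <- model_constants()
  t <- seq(50, 3600, by = 37)
  b <- estimate_distance_band(t, k)
  expect_equal(b$d_max_m / b$d_min_m, rep(3, length(t)))
  expect_true(all(diff(b$d_min_m) > 0))
  expect_true(all(diff(b$d_max_m) > 0))
  expect_true(all(diff(b$d_max_m - b$d_min_m) > 0))  # band widens with distance
  # under non-default speeds the ratio tracks the speed ratio
  k2 <- model_constants(s_min = 1.5, s_max = 6)
  b2 <- estimate_distance_band(600, k2)
  expect_equal(b2$d_max_m / b2$d_min_m, 4)
})

test_that("half-angle rule is a monotone step with the tie going wide", {
  expect_equal(select_half_angle(540), 10)
  expect_equal(select_half_angle(660), 15)
  expect_equal(select_half_angle(600), 15)  # at the threshold: conservative
  t <- seq(60, 1800, by = 30)
  a <- select_half_angle(t)
  expect_true(all(diff(a) >= 0))
  expect_setequal(unique(a), c(10, 15))
  expect_error(select_half_angle(-5), "positive")
})

test_that("trips aggregate into one track per station-individual pair", {
  trips <- data.frame(
    station_id = "BS1", hornet_id = "YB",
    bearing_deg = c(12, 8, 10), round_trip_s = c(610, 700, 655))
  tk <- aggregate_tracks(trips)
  expect_equal(nrow(tk), 1)
  expect_equal(tk$n_trips, 3)
  expect_equal(tk$t_min_s, 610)
  expect_equal(tk$mean_bearing_deg, 10, tolerance = 0.01)
  expect_false(is.na(tk$bearing_dispersion_deg))

  grid <- expand.grid(station_id = c("BS1", "BS2"), hornet_id = c("A", "B"),
                      trip = 1:3, stringsAsFactors = FALSE)
  grid$bearing_deg <- 90
  grid$round_trip_s <- 400 + grid$trip
  tk2 <- aggregate_tracks(grid)
  expect_equal(nrow(tk2), 4)
  expect_equal(tk2$station_id, c("BS1", "BS1", "BS2", "BS2"))  # deterministic order
  expect_equal(unique(tk2$t_min_s), 401)

  expect_error(aggregate_tracks(grid[0, ]), "non-empty")
  bad <- trips; bad$round_trip_s[1] <- -5
  expect_error(aggregate_tracks(bad), "> 0")
})

test_that("usability report names each failed criterion", {
  k <- model_constants()
  expect_true(check_track_usable(make_track(n_trips = 3, t_min_s = 600), k)$usable)
  r2 <- check_track_usable(make_track(n_trips = 2, t_min_s = 600), k)
  expect_false(r2$usable)
  expect_match(r2$reasons, "insufficient trips")
  r3 <- check_track_usable(make_track(n_trips = 5, t_min_s = 40), k)
  expect_false(r3$usable)
  expect_match(r3$reasons, "nest-handling")
  r4 <- check_track_usable(make_track(n_trips = 1, t_min_s = 30), k)
  expect_length(r4$reasons, 2)
})

test_that("usable_tracks partitions and records exclusion reasons", {
  tracks <- rbind(make_track(hornet_id = "H01"),
                  make_track(hornet_id = "H02", n_trips = 2),
                  make_track(hornet_id = "H03", t_min_s = 20))
  ok <- usable_tracks(tracks)
  expect_equal(ok$hornet_id, "H01")
  ex <- attr(ok, "excluded")
  expect_equal(nrow(ex), 2)
  expect_match(ex$reason[ex$hornet_id == "H02"], "insufficient")
  expect_match(ex$reason[ex$hornet_id == "H03"], "nest-handling")
})
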