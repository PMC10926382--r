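sector_area_closed_form <- function(half_angle, d_min, d_max) {
  (2 * half_angle / 360) * pi * (d_max^2 - d_min^2)
}

test_that("sector-annulus polygon area matches the closed form", {
  rg <- build_sector_annulus(c(0, 0), make_track(t_min_s = 345))
  expect_equal(rg$d_min_m, 270)
  expect_equal(rg$d_max_m, 810)
  expect_equal(rg$half_angle_deg, 10)
  expect_equal(rg$area_m2, 32400 * pi, tolerance = 0.005)  # 101,787.6 m2
  # agreement improves as the discretization is refined
  err <- sapply(c(5, 2, 1, 0.25), function(st) {
    r <- build_sector_annulus(c(0, 0), make_track(t_min_s = 345), arc_step = st)
    abs(r$area_m2 - 32400 * pi) / (32400 * pi)
  })
  expect_true(all(diff(err) < 0))
  expect_lt(err[3], 0.005)
})

test_that("polygon vertices obey the band and bearing constraints", {
  st <- c(120, -80)
  tr <- make_track(t_min_s = 700, mean_bearing_deg = 237)
  rg <- build_sector_annulus(st, tr)
  ring <- rg$rings[[1]]
  r <- sqrt((ring$x - st[1])^2 + (ring$y - st[2])^2)
  expect_true(all(r >= rg$d_min_m - 1e-6 & r <= rg$d_max_m + 1e-6))
  b <- atan2(ring$x - st[1], ring$y - st[2]) * 180 / pi
  expect_true(all(angdiff(b, 237) <= rg$half_angle_deg + 1e-6))
  # counter-clockwise orientation (positive shoelace)
  x <- ring$x; y <- ring$y
  shoelace <- 0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
  expect_gt(shoelace, 0)
  expect_equal(rg$area_m2, shoelace, tolerance = 1e-6)
})

test_that("widening the half-angle strictly enlarges the likely area", {
  tr <- make_track(t_min_s = 650)  # long-trip regime
  narrow <- model_constants(angle_short = 10, angle_long = 10)
  wide <- model_constants(angle_short = 10, angle_long = 15)
  a10 <- build_sector_annulus(c(0, 0), tr, narrow)$area_m2
  a15 <- build_sector_annulus(c(0, 0), tr, wide)$area_m2
  expect_gt(a15, a10)
  expect_equal(a15 / a10, 1.5, tolerance = 1e-3)
})

test_that("unusable tracks and bad arc steps are rejected", {
  expect_error(build_sector_annulus(c(0, 0), make_track(n_trips = 2)),
               "not usable")
  expect_error(build_sector_annulus(c(0, 0), make_track(), arc_step = 6),
               "arc_step")
})

test_that("intersection is idempotent, monotone, and order-independent", {
  a <- build_sector_annulus(c(0, 0), make_track(t_min_s = 345, mean_bearing_deg = 0))
  b <- build_sector_annulus(c(300, 100), make_track(
    station_id = "BS2", hornet_id = "H02", t_min_s = 400, mean_bearing_deg = 320))
  c3 <- build_sector_annulus(c(-200, 50), make_track(
    station_id = "BS3", hornet_id = "H03", t_min_s = 380, mean_bearing_deg = 35))
  self <- intersect_regions(list(a, a))
  expect_equal(self$area_m2, a$area_m2, tolerance = 1e-6)
  ab <- intersect_regions(list(a, b))
  expect_equal(ab$kind, "convergent")
  expect_lte(ab$area_m2, min(a$area_m2, b$area_m2))
  expect_gt(ab$area_m2, 0)
  expect_equal(nrow(ab$provenance), 2)
  # commutative and associative at the point-set level
  perms <- list(c(1, 2, 3), c(3, 1, 2), c(2, 3, 1))
  areas <- sapply(perms, function(p) intersect_regions(list(a, b, c3)[p])$area_m2)
  expect_lt(diff(range(areas)) / max(areas[1], 1e-12), 1e-6)
})

test_that("disjoint regions give an explicit empty convergence, not an error", {
  a <- build_sector_annulus(c(0, 0), make_track(mean_bearing_deg = 0))
  b <- build_sector_annulus(c(0, 0), make_track(hornet_id = "H02",
                                                mean_bearing_deg = 180))
  out <- intersect_regions(list(a, b))
  expect_length(out$rings, 0)
  expect_equal(out$area_m2, 0)
  expect_equal(out$diagnostic, "no convergence")
  expect_false(containment_check(out, c(0, 400)))
})

test_that("regions in different frames refuse to intersect", {
  fr1 <- local_frame(42, -8)
  fr2 <- local_frame(43, -8)
  a <- build_sector_annulus(c(0, 0), make_track(), frame = fr1)
  b <- build_sector_annulus(c(0, 0), make_track(), frame = fr2)
  expect_error(intersect_regions(list(a, b)), "different local frames")
})

test_that("containment agrees with the region definition", {
  st <- c(0, 0)
  rg <- build_sector_annulus(st, make_track(t_min_s = 345, mean_bearing_deg = 0))
  expect_false(containment_check(rg, st))                 # apex: r = 0 < d_min
  expect_true(containment_check(rg, c(0, 540)))           # mid-band on axis
  expect_true(containment_check(rg, region_centroid(rg))) # centroid of a convex wedge
  expect_false(containment_check(rg, c(0, 900)))          # beyond d_max
  expect_false(containment_check(rg, c(500, 0)))          # 90 deg off-bearing
})

test_that("Monte-Carlo point classification reproduces the polygon area", {
  rg <- build_sector_annulus(c(0, 0), make_track(t_min_s = 345, mean_bearing_deg = 30))
  ring <- rg$rings[[1]]
  xr <- range(ring$x); yr <- range(ring$y)
  set.seed(314)
  n <- 20000
  px <- runif(n, xr[1], xr[2]); py <- runif(n, yr[1], yr[2])
  inside <- vapply(seq_len(n), function(i) containment_check(rg, c(px[i], py[i])),
                   logical(1))
  bbox <- diff(xr) * diff(yr)
  p <- mean(inside)
  est <- p * bbox
  se <- bbox * sqrt(p * (1 - p) / n)
  expect_lt(abs(est - rg$area_m2), 3 * se)
})

test_that("second-station suggestion is outside, within the margin band, deterministic", {
  rg <- build_sector_annulus(c(0, 0), make_track(t_min_s = 345, mean_bearing_deg = 40))
  p1 <- suggest_second_station(rg, margin = 50)
  p2 <- suggest_second_station(rg, margin = 50)
  expect_identical(p1, p2)
  expect_false(containment_check(rg, p1))
  d <- vespalocate:::dist_point_rings(p1, rg$rings)
  expect_gte(d, 50)
  expect_lte(d, 100)
  # lies on the side of the mean-bearing axis (beyond the far arc)
  expect_lt(angdiff(atan2(p1[["x"]], p1[["y"]]) * 180 / pi, 40), 1)
  expect_error(suggest_second_station(rg, margin = -1), "margin")
})
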