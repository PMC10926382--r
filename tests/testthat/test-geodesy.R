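test_that("azimuthal-equidistant frame maps known offsets correctly", {
  fr <- local_frame(0, 0)
  # origin maps to itself
  o <- to_local_frame(0, 0, fr)
  expect_equal(unlist(o), c(x = 0, y = 0))
  # 0.001 degree due north at the equator ~ one thousandth of a degree of arc
  p <- to_local_frame(0.001, 0, fr)
  expect_equal(p$x, 0, tolerance = 1e-9)
  expect_equal(p$y, 111.32, tolerance = 0.005)  # arc-length oracle, 0.5%
  # due east at the equator is symmetric
  q <- to_local_frame(0, 0.001, fr)
  expect_equal(q$x, p$y, tolerance = 1e-9)
})

test_that("projection round-trips within 1e-6 degrees at 10 km scale", {
  set.seed(42)
  fr <- local_frame(42.2, -8.7)  # mid-latitude origin
  lat <- 42.2 + runif(50, -0.08, 0.08)
  lon <- -8.7 + runif(50, -0.1, 0.1)
  xy <- to_local_frame(lat, lon, fr)
  back <- from_local_frame(xy$x, xy$y, fr)
  expect_lt(max(abs(back$lat - lat)), 1e-6)
  expect_lt(max(abs(back$lon - lon)), 1e-6)
})

test_that("distance from the origin agrees with an independent geodesic oracle", {
  skip_if_not_installed("geosphere")
  set.seed(7)
  fr <- local_frame(42.2, -8.7)
  lat <- 42.2 + runif(20, -0.03, 0.03)
  lon <- -8.7 + runif(20, -0.04, 0.04)
  xy <- to_local_frame(lat, lon, fr)
  d_mine <- sqrt(xy$x^2 + xy$y^2)
  d_ref <- geosphere::distGeo(cbind(-8.7, 42.2), cbind(lon, lat))
  expect_lt(max(abs(d_mine - d_ref) / d_ref), 0.005)
})

test_that("points far from the frame origin are rejected", {
  fr <- local_frame(0, 0)
  expect_error(to_local_frame(1, 0, fr), "farther")
  expect_error(to_local_frame(91, 0, fr), "latitude")
})

test_that("bearing normalization wraps into [0, 360) and is idempotent", {
  expect_equal(normalize_bearing(370), 10)
  expect_equal(normalize_bearing(-45), 315)
  expect_equal(normalize_bearing(0), 0)
  expect_equal(normalize_bearing(360), 0)
  x <- c(-720.5, -1, 0, 359.999, 1234)
  expect_equal(normalize_bearing(normalize_bearing(x)), normalize_bearing(x))
  expect_true(all(normalize_bearing(x) >= 0 & normalize_bearing(x) < 360))
  expect_error(normalize_bearing(NA_real_), "finite")
  expect_error(normalize_bearing(Inf), "finite")
})

test_that("circular mean handles the north wrap and degenerate input", {
  expect_equal(circular_mean(c(350, 10)), 0)
  expect_equal(circular_mean(c(10, 10, 10)), 10)
  expect_equal(circular_mean(c(0, 90)), 45)
  expect_error(circular_mean(numeric(0)), "at least one")
  expect_error(circular_mean(c(0, 180)), "antipodal")
})

test_that("circular mean is rotation-equivariant", {
  set.seed(99)
  for (i in 1:25) {
    b <- runif(sample(2:8, 1), 0, 60) + runif(1, 0, 300)  # clustered bearings
    shift <- runif(1, -720, 720)
    m1 <- circular_mean(normalize_bearing(b + shift))
    m2 <- normalize_bearing(circular_mean(b) + shift)
    expect_lt(angdiff(m1, m2), 1e-6)
  }
})

test_that("circular dispersion matches the resultant-length formula", {
  expect_equal(circular_dispersion(c(10, 10)), 0)
  expect_equal(circular_dispersion(c(0, 180)), Inf)
  b <- c(355, 5, 0)
  # independent oracle: sqrt(-2 log R) on unit vectors, evaluated directly
  th <- b * pi / 180
  r <- sqrt(mean(sin(th))^2 + mean(cos(th))^2)
  expect_equal(circular_dispersion(b), sqrt(-2 * log(r)) * 180 / pi,
               tolerance = 1e-12)
  expect_error(circular_dispersion(5), "at least two")
})
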