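# Mean Earth radius (IUGG), metres. At the sub-3-km scale of the method the
# sphere/ellipsoid discrepancy is far below the 3x flight-speed bracket.
EARTH_RADIUS_M <- 6371008.8

# Points farther than this from the frame origin almost certainly indicate
# swapped or mis-entered coordinates; the method operates at a few km.
MAX_FRAME_RANGE_M <- 50000

#' Define a local planar reference frame
#'
#' Observations can be supplied either in geographic coordinates (WGS84
#' lat/lon) or directly in a planar metric frame (x east, y north, metres).
#' All geometry is computed in the planar frame; geographic input is
#' projected with an azimuthal equidistant projection centred on the frame
#' origin, so distances from the origin are exact and pairwise distortion is
#' negligible at the working scale of a few kilometres.
#'
#' @param origin_lat,origin_lon Origin of the frame in decimal degrees
#'   (required for `mode = "geographic"`).
#' @param mode `"geographic"` (project lat/lon) or `"planar"` (input already
#'   metric; no origin needed).
#' @return An object of class `local_frame`.
#' @export
local_frame <- function(origin_lat = NULL, origin_lon = NULL,
                        mode = c("geographic", "planar")) {
  mode <- match.arg(mode)
  if (mode == "geographic") {
    if (is.null(origin_lat) || is.null(origin_lon)) {
      stop("geographic frame requires origin_lat and origin_lon")
    }
    stopifnot(is.finite(origin_lat), is.finite(origin_lon))
    if (abs(origin_lat) > 90 || abs(origin_lon) > 180) {
      stop("frame origin outside valid lat/lon range")
    }
  } else {
    origin_lat <- NULL
    origin_lon <- NULL
  }
  structure(list(mode = mode, origin_lat = origin_lat, origin_lon = origin_lon),
            class = "local_frame")
}

#' @export
print.local_frame <- function(x, ...) {
  if (x$mode == "planar") {
    cat("<local_frame> planar (x east / y north, metres)\n")
  } else {
    cat(sprintf("<local_frame> azimuthal equidistant, origin %.6f N %.6f E\n",
                x$origin_lat, x$origin_lon))
  }
  invisible(x)
}

same_frame <- function(a, b, tol = 1e-9) {
  if (!inherits(a, "local_frame") || !inherits(b, "local_frame")) return(FALSE)
  if (a$mode != b$mode) return(FALSE)
  if (a$mode == "planar") return(TRUE)
  abs(a$origin_lat - b$origin_lat) < tol && abs(a$origin_lon - b$origin_lon) < tol
}

#' Project geographic points into a local frame
#'
#' Azimuthal equidistant projection on a sphere of mean Earth radius,
#' centred on the frame origin: `x` is metres east, `y` metres north.
#'
#' @param lat,lon Numeric vectors, decimal degrees WGS84.
#' @param frame A geographic [local_frame()].
#' @return A data frame with columns `x`, `y` (metres).
#' @export
to_local_frame <- function(lat, lon, frame) {
  stopifnot(inherits(frame, "local_frame"))
  if (frame$mode != "geographic") stop("frame is planar; nothing to project")
  if (length(lat) != length(lon)) stop("lat and lon must have equal length")
  if (any(!is.finite(lat)) || any(!is.finite(lon))) stop("non-finite coordinates")
  if (any(abs(lat) > 90) || any(abs(lon) > 180)) {
    stop("latitude must be in [-90, 90] and longitude in [-180, 180]")
  }
  phi0 <- frame$origin_lat * pi / 180
  lam0 <- frame$origin_lon * pi / 180
  phi <- lat * pi / 180
  dl <- lon * pi / 180 - lam0
  # central angle and forward azimuth from the origin
  cosc <- pmin(1, pmax(-1, sin(phi0) * sin(phi) + cos(phi0) * cos(phi) * cos(dl)))
  c <- acos(cosc)
  az <- atan2(sin(dl) * cos(phi),
              cos(phi0) * sin(phi) - sin(phi0) * cos(phi) * cos(dl))
  d <- EARTH_RADIUS_M * c
  if (any(d > MAX_FRAME_RANGE_M)) {
    stop(sprintf("point(s) farther than %g km from frame origin; check coordinates",
                 MAX_FRAME_RANGE_M / 1000))
  }
  data.frame(x = d * sin(az), y = d * cos(az))
}

#' Inverse of [to_local_frame()]
#'
#' @param x,y Numeric vectors, metres east/north of the frame origin.
#' @param frame A geographic [local_frame()].
#' @return A data frame with columns `lat`, `lon` (decimal degrees).
#' @export
from_local_frame <- function(x, y, frame) {
  stopifnot(inherits(frame, "local_frame"))
  if (frame$mode != "geographic") stop("frame is planar; nothing to unproject")
  if (length(x) != length(y)) stop("x and y must have equal length")
  phi0 <- frame$origin_lat * pi / 180
  lam0 <- frame$origin_lon * pi / 180
  d <- sqrt(x^2 + y^2)
  c <- d / EARTH_RADIUS_M
  az <- atan2(x, y)
  sinphi <- pmin(1, pmax(-1, sin(phi0) * cos(c) + cos(phi0) * sin(c) * cos(az)))
  phi <- asin(sinphi)
  lam <- lam0 + atan2(sin(az) * sin(c) * cos(phi0),
                      cos(c) - sin(phi0) * sinphi)
  out <- data.frame(lat = phi * 180 / pi, lon = lam * 180 / pi)
  # d == 0 makes the azimuth undefined; pin to the origin exactly
  out$lat[d == 0] <- frame$origin_lat
  out$lon[d == 0] <- frame$origin_lon
  out$lon <- ((out$lon + 180) %% 360) - 180
  out
}

#' Normalize a compass bearing to [0, 360)
#'
#' Bearings are compass bearings: degrees clockwise from true north.
#'
#' @param raw Numeric vector of bearings in degrees (any real value).
#' @return Bearings in `[0, 360)`, congruent to `raw` modulo 360.
#' @export
normalize_bearing <- function(raw) {
  if (any(!is.finite(raw))) stop("bearings must be finite")
  b <- raw %% 360
  b[b >= 360 | b < 0] <- 0  # guard against floating-point edge of the modulo
  b
}

#' Circular (unit-vector) mean of compass bearings
#'
#' The mean vanishing direction of an individual is computed as the
#' direction of the resultant of unit vectors, not the arithmetic mean of
#' degree values, which fails across the 0/360 wrap (e.g. 350 and 10).
#'
#' @param bearings Numeric vector of bearings in degrees.
#' @return Mean bearing in `[0, 360)`.
#' @export
circular_mean <- function(bearings) {
  if (length(bearings) == 0) stop("at least one bearing is required")
  b <- normalize_bearing(bearings)
  th <- b * pi / 180
  s <- mean(sin(th)); cc <- mean(cos(th))
  if (sqrt(s^2 + cc^2) < 1e-9) {
    stop("bearings nearly antipodal: mean direction undefined (inconsistent observations)")
  }
  normalize_bearing(atan2(s, cc) * 180 / pi)
}

#' Circular standard deviation of compass bearings
#'
#' Diagnostic for how consistent an individual's vanishing directions are:
#' `sqrt(-2 log R)` (in degrees), where `R` is the mean resultant length.
#' Returns `Inf` when the bearings are balanced/antipodal (`R` ~ 0).
#'
#' @param bearings Numeric vector of at least two bearings in degrees.
#' @return Circular standard deviation in degrees (`>= 0`).
#' @export
circular_dispersion <- function(bearings) {
  if (length(bearings) < 2) stop("at least two bearings are required")
  b <- normalize_bearing(bearings)
  th <- b * pi / 180
  r <- sqrt(mean(sin(th))^2 + mean(cos(th))^2)
  if (r < 1e-9) return(Inf)
  if (r >= 1 - 1e-12) return(0)  # identical bearings up to rounding
  sqrt(-2 * log(r)) * 180 / pi
}

# Compass bearing (degrees clockwise from north) of the segment from -> to,
# in the local planar frame.
planar_bearing <- function(from_x, from_y, to_x, to_y) {
  dx <- to_x - from_x
  dy <- to_y - from_y
  if (any(dx == 0 & dy == 0)) stop("bearing undefined for coincident points")
  normalize_bearing(atan2(dx, dy) * 180 / pi)
}

# Smallest absolute angular difference between two bearings, degrees in [0, 180].
bearing_difference <- function(a, b) {
  d <- abs(normalize_bearing(a) - normalize_bearing(b)) %% 360
  pmin(d, 360 - d)
}
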