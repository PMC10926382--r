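#' Model constants for the distance-band estimator
#'
#' Field-calibrated constants of the nest-distance model. A marked hornet's
#' shortest bait-nest-bait round trip `t_t` is split into two flight legs
#' plus a fixed time `t_nest` spent on the nest; bracketing flight speeds
#' convert the flight time into a distance band:
#' `d = ((t_t - t_nest)/2) * s`, evaluated at `s_min` and `s_max`.
#'
#' @param t_nest Time spent on the nest per visit, seconds (default 45,
#'   estimated in the field from a sample of 20 trips).
#' @param s_min Minimum flight speed, m/s (default 1.8, field mean of 30
#'   observed flights of loaded foragers).
#' @param s_max Maximum flight speed, m/s (default 5.4, maximum reported for
#'   homing hornets tracked by harmonic radar; deliberately conservative —
#'   it enlarges the search area rather than risking missing the nest).
#' @param angle_short Sector half-angle, degrees, for short trips (default 10).
#' @param angle_long Sector half-angle, degrees, for long trips (default 15):
#'   the farther the nest, the more a forager may deviate from its mean
#'   vanishing direction, so the sector is widened.
#' @param trip_time_threshold Round-trip time separating the short/long angle
#'   regimes, seconds (default 600, i.e. 10 minutes).
#' @param min_trips Minimum number of recorded round trips before an
#'   individual's track is used (default 3).
#' @return An object of class `model_constants`.
#' @export
model_constants <- function(t_nest = 45, s_min = 1.8, s_max = 5.4,
                            angle_short = 10, angle_long = 15,
                            trip_time_threshold = 600, min_trips = 3) {
  vals <- list(t_nest = t_nest, s_min = s_min, s_max = s_max,
               angle_short = angle_short, angle_long = angle_long,
               trip_time_threshold = trip_time_threshold,
               min_trips = min_trips)
  for (nm in names(vals)) {
    v <- vals[[nm]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      stop(sprintf("constant '%s' must be a single finite number", nm))
    }
  }
  if (!(s_min > 0 && s_min < s_max)) stop("need 0 < s_min < s_max")
  if (t_nest < 0) stop("t_nest must be >= 0")
  if (!(angle_short > 0 && angle_short <= angle_long && angle_long < 90)) {
    stop("need 0 < angle_short <= angle_long < 90")
  }
  if (trip_time_threshold <= t_nest) stop("trip_time_threshold must exceed t_nest")
  if (min_trips < 1) stop("min_trips must be >= 1")
  structure(vals, class = "model_constants")
}

#' @export
print.model_constants <- function(x, ...) {
  cat("Distance-band model constants:\n")
  cat(sprintf("  nest-handling time t_nest    %g s\n", x$t_nest))
  cat(sprintf("  flight speeds s_min / s_max  %g / %g m/s\n", x$s_min, x$s_max))
  cat(sprintf("  sector half-angle            %g deg (<%g s) / %g deg\n",
              x$angle_short, x$trip_time_threshold, x$angle_long))
  cat(sprintf("  minimum trips per individual %d\n", as.integer(x$min_trips)))
  invisible(x)
}

validate_trips_df <- function(trips) {
  if (!is.data.frame(trips) || nrow(trips) == 0) {
    stop("trip observations must be a non-empty data frame")
  }
  need <- c("station_id", "hornet_id", "bearing_deg", "round_trip_s")
  miss <- setdiff(need, names(trips))
  if (length(miss)) stop("missing trip column(s): ", paste(miss, collapse = ", "))
  if (any(!is.finite(trips$round_trip_s)) || any(trips$round_trip_s <= 0)) {
    stop("round_trip_s must be finite and > 0")
  }
  if (any(!is.finite(trips$bearing_deg))) stop("bearing_deg must be finite")
  trips
}

#' Aggregate trip observations into per-individual tracks
#'
#' One track per (station, marked individual) pair. Per-individual
#' aggregation is essential: in high-density areas a single bait can
#' attract hornets from multiple nests, so times and bearings are never
#' pooled across individuals.
#'
#' @param trips Data frame with columns `station_id`, `hornet_id`,
#'   `bearing_deg`, `round_trip_s`.
#' @return Data frame with one row per track, ordered by station then
#'   hornet id: `station_id`, `hornet_id`, `n_trips`, `t_min_s`,
#'   `mean_bearing_deg` (circular mean), `bearing_dispersion_deg`
#'   (circular SD; `NA` for a single trip).
#' @export
aggregate_tracks <- function(trips) {
  trips <- validate_trips_df(trips)
  trips$bearing_deg <- normalize_bearing(trips$bearing_deg)
  key <- interaction(trips$station_id, trips$hornet_id, drop = TRUE, sep = "\r")
  groups <- split(trips, key)
  rows <- lapply(groups, function(g) {
    data.frame(
      station_id = as.character(g$station_id[1]),
      hornet_id = as.character(g$hornet_id[1]),
      n_trips = nrow(g),
      t_min_s = min(g$round_trip_s),
      mean_bearing_deg = circular_mean(g$bearing_deg),
      bearing_dispersion_deg =
        if (nrow(g) >= 2) circular_dispersion(g$bearing_deg) else NA_real_,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$station_id, out$hornet_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Estimate the nest distance band from the shortest round-trip time
#'
#' `d_min = ((t_min - t_nest)/2) * s_min` and
#' `d_max = ((t_min - t_nest)/2) * s_max`: the flight portion of the round
#' trip, halved under the assumption of symmetric straight-line legs, times
#' the bracketing flight speeds. The ratio `d_max/d_min` is always
#' `s_max/s_min` (3 under the defaults).
#'
#' @param t_min Shortest observed round-trip time(s), seconds; must exceed
#'   `constants$t_nest` (a trip no longer than the nest-handling time means
#'   a mistimed observation or confused identity).
#' @param constants A [model_constants()] object.
#' @return Data frame with columns `d_min_m`, `d_max_m` (metres).
#' @export
estimate_distance_band <- function(t_min, constants = model_constants()) {
  stopifnot(inherits(constants, "model_constants"))
  if (any(!is.finite(t_min))) stop("t_min must be finite")
  if (any(t_min <= constants$t_nest)) {
    stop(sprintf(
      "infeasible trip: round-trip time (%g s) does not exceed nest-handling time (%g s)",
      min(t_min), constants$t_nest))
  }
  flight <- (t_min - constants$t_nest) / 2
  data.frame(d_min_m = flight * constants$s_min,
             d_max_m = flight * constants$s_max)
}

#' Select the sector half-angle for a track
#'
#' 10 degrees for minimum round-trip times shorter than 10 minutes, 15
#' degrees otherwise. A time of exactly the threshold takes the larger
#' angle: it is the conservative choice (a wider sector can only enlarge
#' the search area, never exclude the nest).
#'
#' @param t_min Shortest observed round-trip time(s), seconds.
#' @param constants A [model_constants()] object.
#' @return Half-angle(s) in degrees.
#' @export
select_half_angle <- function(t_min, constants = model_constants()) {
  stopifnot(inherits(constants, "model_constants"))
  if (any(!is.finite(t_min)) || any(t_min <= 0)) stop("t_min must be positive")
  ifelse(t_min < constants$trip_time_threshold,
         constants$angle_short, constants$angle_long)
}

#' Check whether a track can be used for localization
#'
#' A track is usable when the individual completed at least
#' `constants$min_trips` round trips and its shortest time exceeds the
#' nest-handling time. Returns a report, never an error, so field crews can
#' audit every exclusion.
#'
#' @param track A single-row data frame (or list) with at least `n_trips`
#'   and `t_min_s`.
#' @param constants A [model_constants()] object.
#' @return A list with `usable` (logical) and `reasons` (character vector,
#'   empty when usable).
#' @export
check_track_usable <- function(track, constants = model_constants()) {
  stopifnot(inherits(constants, "model_constants"))
  n <- track$n_trips
  tmin <- track$t_min_s
  if (is.null(n) || is.null(tmin) || length(n) != 1 || length(tmin) != 1) {
    stop("track must provide single n_trips and t_min_s values")
  }
  reasons <- character(0)
  if (n < constants$min_trips) {
    reasons <- c(reasons, sprintf("insufficient trips (%d < %d)",
                                  as.integer(n), as.integer(constants$min_trips)))
  }
  if (tmin <= constants$t_nest) {
    reasons <- c(reasons, sprintf(
      "trip shorter than nest-handling time (%g s <= %g s)", tmin, constants$t_nest))
  }
  list(usable = length(reasons) == 0, reasons = reasons)
}

#' Split tracks into usable and excluded sets
#'
#' @param tracks Output of [aggregate_tracks()].
#' @param constants A [model_constants()] object.
#' @return The usable subset of `tracks`; the excluded rows, with a
#'   `reason` column, are attached as attribute `"excluded"`.
#' @export
usable_tracks <- function(tracks, constants = model_constants()) {
  if (!is.data.frame(tracks) || nrow(tracks) == 0) stop("no tracks supplied")
  reports <- lapply(seq_len(nrow(tracks)),
                    function(i) check_track_usable(tracks[i, ], constants))
  ok <- vapply(reports, `[[`, logical(1), "usable")
  excluded <- tracks[!ok, , drop = FALSE]
  if (nrow(excluded)) {
    excluded$reason <- vapply(reports[!ok],
                              function(r) paste(r$reasons, collapse = "; "),
                              character(1))
  } else {
    excluded$reason <- character(0)
  }
  rownames(excluded) <- NULL
  out <- tracks[ok, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "excluded") <- excluded
  out
}
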