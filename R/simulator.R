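# Truncated-normal draw that degrades gracefully to a constant when sd = 0
# (the noise-free limit used in validation).
rtrunc_or_const <- function(n, mean, sd, lower, upper) {
  if (sd <= 0) return(rep(min(max(mean, lower), upper), n))
  truncnorm::rtruncnorm(n, a = lower, b = upper, mean = mean, sd = sd)
}

#' Define a synthetic foraging scenario
#'
#' Ground truth for end-to-end validation: a known nest position, bait
#' stations, and a noise model for the repeated provisioning trips of
#' marked central-place foragers. Defaults emulate field conditions:
#' flight speed is a truncated normal centred on 2.7 m/s (the maximum
#' flight speed estimated in the field, taken as a central loaded-flight
#' speed between the model's bracketing constants 1.8 and 5.4 m/s) with
#' sd 0.5; nest-handling time 45 +/- 10 s floored at 5 s; vanishing-bearing
#' scatter sd 3 degrees, comfortably inside the 10-degree sector half-angle.
#'
#' @param true_nest Numeric length-2 (x, y) of the nest, metres, local frame.
#' @param stations Data frame with columns `station_id`, `x`, `y` (metres).
#' @param n_hornets_per_station Marked individuals per station.
#' @param trips_per_hornet Recorded round trips per individual (>= 3, the
#'   usability minimum).
#' @param speed_mean,speed_sd,speed_min,speed_max Truncated-normal flight
#'   speed model, m/s; outbound and return speeds are drawn independently
#'   (the load changes between legs).
#' @param handling_mean,handling_sd,handling_min Truncated-normal (lower
#'   bound only) time on the nest, seconds.
#' @param bearing_noise_sd SD of Gaussian scatter added to the true
#'   station-to-nest bearing, degrees.
#' @param seed Integer RNG seed; every draw in the scenario flows from it.
#' @return An object of class `simulation_scenario`.
#' @export
simulation_scenario <- function(true_nest, stations,
                                n_hornets_per_station = 2,
                                trips_per_hornet = 5,
                                speed_mean = 2.7, speed_sd = 0.5,
                                speed_min = 1.8, speed_max = 5.4,
                                handling_mean = 45, handling_sd = 10,
                                handling_min = 5,
                                bearing_noise_sd = 3, seed = 1) {
  stopifnot(length(true_nest) == 2, all(is.finite(true_nest)))
  if (!is.data.frame(stations) ||
      !all(c("station_id", "x", "y") %in% names(stations)) ||
      nrow(stations) == 0) {
    stop("stations must be a data frame with station_id, x, y")
  }
  if (anyDuplicated(stations$station_id)) stop("duplicate station ids")
  if (trips_per_hornet < 3) stop("trips_per_hornet must be >= 3")
  if (n_hornets_per_station < 1) stop("n_hornets_per_station must be >= 1")
  if (!(speed_min > 0 && speed_min < speed_max)) stop("need 0 < speed_min < speed_max")
  if (speed_mean < speed_min || speed_mean > speed_max) {
    stop("speed_mean must lie within [speed_min, speed_max]")
  }
  if (speed_sd < 0 || handling_sd < 0 || bearing_noise_sd < 0) {
    stop("noise standard deviations must be >= 0")
  }
  if (handling_min <= 0 || handling_mean < handling_min) {
    stop("need 0 < handling_min <= handling_mean")
  }
  d <- sqrt((stations$x - true_nest[1])^2 + (stations$y - true_nest[2])^2)
  if (any(d < 1e-9)) stop("degenerate scenario: nest coincides with a bait station")
  structure(list(
    true_nest = c(x = true_nest[1], y = true_nest[2]), stations = stations,
    n_hornets_per_station = n_hornets_per_station,
    trips_per_hornet = trips_per_hornet,
    speed_mean = speed_mean, speed_sd = speed_sd,
    speed_min = speed_min, speed_max = speed_max,
    handling_mean = handling_mean, handling_sd = handling_sd,
    handling_min = handling_min,
    bearing_noise_sd = bearing_noise_sd, seed = as.integer(seed)
  ), class = "simulation_scenario")
}

#' Simulate marked-hornet round trips from a known nest
#'
#' Each trip of each marked individual draws independent outbound and
#' return flight speeds and a nest-handling time, giving
#' `round_trip_s = d/v_out + handling + d/v_back` for the true
#' station-nest distance `d`, and a vanishing bearing equal to the true
#' station-to-nest bearing plus Gaussian scatter. Rows are shuffled
#' deterministically by the scenario seed, emulating interleaved field
#' observation of several individuals.
#'
#' @param scenario A [simulation_scenario()].
#' @return Data frame of trip observations (`station_id`, `hornet_id`,
#'   `bearing_deg`, `round_trip_s`), reproducible from the scenario seed.
#' @export
simulate_trips <- function(scenario) {
  stopifnot(inherits(scenario, "simulation_scenario"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(scenario$seed)
  st <- scenario$stations
  rows <- list()
  hornet_no <- 0L
  for (i in seq_len(nrow(st))) {
    dx <- scenario$true_nest[["x"]] - st$x[i]
    dy <- scenario$true_nest[["y"]] - st$y[i]
    dist <- sqrt(dx^2 + dy^2)
    true_bearing <- planar_bearing(st$x[i], st$y[i],
                                   scenario$true_nest[["x"]], scenario$true_nest[["y"]])
    for (h in seq_len(scenario$n_hornets_per_station)) {
      hornet_no <- hornet_no + 1L
      n <- scenario$trips_per_hornet
      v_out <- rtrunc_or_const(n, scenario$speed_mean, scenario$speed_sd,
                               scenario$speed_min, scenario$speed_max)
      v_back <- rtrunc_or_const(n, scenario$speed_mean, scenario$speed_sd,
                                scenario$speed_min, scenario$speed_max)
      handling <- rtrunc_or_const(n, scenario$handling_mean, scenario$handling_sd,
                                  scenario$handling_min, Inf)
      bearing <- normalize_bearing(
        true_bearing + stats::rnorm(n, 0, scenario$bearing_noise_sd))
      rows[[length(rows) + 1L]] <- data.frame(
        station_id = as.character(st$station_id[i]),
        hornet_id = sprintf("H%02d", hornet_no),
        bearing_deg = bearing,
        round_trip_s = dist / v_out + handling + dist / v_back,
        stringsAsFactors = FALSE
      )
    }
  }
  out <- do.call(rbind, rows)
  out <- out[sample(nrow(out)), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# Pick, per station, the track whose vanishing directions are most
# consistent (smallest circular dispersion; ties broken by id order) —
# the analogue of focusing on "one individual with consistent measurements".
best_track_per_station <- function(tracks) {
  picks <- lapply(split(tracks, tracks$station_id), function(g) {
    disp <- ifelse(is.na(g$bearing_dispersion_deg), Inf, g$bearing_dispersion_deg)
    g[order(disp, g$hornet_id)[1], , drop = FALSE]
  })
  out <- do.call(rbind, picks)
  rownames(out) <- NULL
  out
}

#' Parameter-recovery experiment
#'
#' Repeatedly simulates a scenario, runs the full localization pipeline
#' (aggregate tracks, usability filter, sector-annulus regions, convergent
#' intersection across stations), and records whether the true nest falls
#' in each region. Replicate `r` reuses the scenario with seed
#' `seed + r`, so the whole experiment is reproducible.
#'
#' @param scenario A [simulation_scenario()].
#' @param constants A [model_constants()] object.
#' @param replicates Number of independent replicates (>= 1).
#' @param arc_step Polygon discretization, degrees per vertex.
#' @return A list of class `recovery_report`: `replicates` (per-replicate
#'   data frame with counts, areas and containment flags),
#'   `single_containment` / `convergent_containment` frequencies, and mean
#'   areas.
#' @export
recovery_experiment <- function(scenario, constants = model_constants(),
                                replicates = 200, arc_step = 1) {
  stopifnot(inherits(scenario, "simulation_scenario"), replicates >= 1)
  frame <- local_frame(mode = "planar")
  st <- scenario$stations
  nest <- c(scenario$true_nest[["x"]], scenario$true_nest[["y"]])
  res <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    sc <- scenario
    sc$seed <- scenario$seed + r
    trips <- simulate_trips(sc)
    tracks <- usable_tracks(aggregate_tracks(trips), constants)
    regions <- lapply(seq_len(nrow(tracks)), function(i) {
      tr <- tracks[i, ]
      xy <- c(st$x[st$station_id == tr$station_id],
              st$y[st$station_id == tr$station_id])
      build_sector_annulus(xy, tr, constants, arc_step = arc_step, frame = frame)
    })
    contained <- vapply(regions, containment_check, logical(1), point = nest)
    conv_area <- NA_real_
    conv_contained <- NA
    if (length(unique(tracks$station_id)) >= 2) {
      best <- best_track_per_station(tracks)
      best_regions <- regions[match(
        paste(best$station_id, best$hornet_id),
        paste(tracks$station_id, tracks$hornet_id))]
      conv <- intersect_regions(best_regions)
      conv_area <- conv$area_m2
      conv_contained <- containment_check(conv, nest)
    }
    res[[r]] <- data.frame(
      replicate = r, n_tracks = nrow(tracks),
      n_contained = sum(contained),
      mean_single_area_m2 = mean(vapply(regions, `[[`, numeric(1), "area_m2")),
      convergent_area_m2 = conv_area,
      convergent_contains = conv_contained
    )
  }
  reps <- do.call(rbind, res)
  structure(list(
    replicates = reps,
    single_containment = sum(reps$n_contained) / sum(reps$n_tracks),
    convergent_containment = mean(reps$convergent_contains, na.rm = TRUE),
    mean_single_area_m2 = mean(reps$mean_single_area_m2),
    mean_convergent_area_m2 = mean(reps$convergent_area_m2, na.rm = TRUE),
    n_empty_convergent = sum(reps$convergent_area_m2 == 0, na.rm = TRUE)
  ), class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  n <- nrow(x$replicates)
  cat(sprintf("Recovery experiment: %d replicates\n", n))
  cat(sprintf("  single-track containment   %.3f\n", x$single_containment))
  if (!all(is.na(x$replicates$convergent_contains))) {
    cat(sprintf("  convergent containment     %.3f\n", x$convergent_containment))
    cat(sprintf("  mean area single/convergent  %.0f / %.0f m2\n",
                x$mean_single_area_m2, x$mean_convergent_area_m2))
    if (x$n_empty_convergent > 0) {
      cat(sprintf("  empty convergences         %d (consider angle_long on all tracks)\n",
                  x$n_empty_convergent))
    }
  }
  invisible(x)
}
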