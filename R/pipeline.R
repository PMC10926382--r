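#' Run the full Phase-1 localization pipeline
#'
#' Aggregates trip observations into per-individual tracks, filters them by
#' the usability rules (minimum trip count, feasible minimum time), builds
#' a sector-annulus likely area for every usable track, and intersects
#' regions across bait stations into convergent areas. With a single
#' station it instead suggests where to place a second one.
#'
#' Cross-station intersections are computed pairwise for every pair of
#' single-track regions from different stations; regions from one station
#' are never intersected with each other (two individuals at one bait may
#' come from different nests). When the trips table carries an optional
#' `nest_hypothesis` column, only tracks sharing a hypothesis are
#' intersected. When three or more stations contribute, the full
#' intersection of the most consistent track per station is reported as
#' well.
#'
#' @param stations Data frame from [read_stations()] (or equivalent).
#' @param trips Data frame from [read_trips()] (or equivalent).
#' @param constants A [model_constants()] object.
#' @param crs_mode `"geographic"` (stations carry lat/lon) or `"planar"`
#'   (stations carry x_m/y_m).
#' @param arc_step Polygon discretization, degrees per vertex, in (0, 5].
#' @param margin Clearance for the second-station suggestion, metres.
#' @param quiet Suppress progress messages.
#' @return A list of class `nest_search`: `frame`, `tracks`, `excluded`,
#'   `regions` (single-track), `convergent` (list, possibly empty),
#'   `suggestion` (x/y or NULL), `station_xy`.
#' @export
locate_nest <- function(stations, trips, constants = model_constants(),
                        crs_mode = c("geographic", "planar"),
                        arc_step = 1, margin = 50, quiet = FALSE) {
  crs_mode <- match.arg(crs_mode)
  say <- function(...) if (!quiet) message(sprintf(...))
  if (crs_mode == "geographic") {
    frame <- local_frame(mean(stations$lat), mean(stations$lon))
    xy <- to_local_frame(stations$lat, stations$lon, frame)
    say("INFO frame: azimuthal equidistant, origin %.6f N %.6f E",
        frame$origin_lat, frame$origin_lon)
  } else {
    frame <- local_frame(mode = "planar")
    xy <- data.frame(x = stations$x_m, y = stations$y_m)
    say("INFO frame: planar metric input")
  }
  station_xy <- data.frame(station_id = as.character(stations$station_id),
                           x = xy$x, y = xy$y, stringsAsFactors = FALSE)
  unknown <- setdiff(unique(trips$station_id), station_xy$station_id)
  if (length(unknown)) {
    stop("trips reference unknown station id(s): ", paste(unknown, collapse = ", "))
  }
  tracks_all <- aggregate_tracks(trips)
  say("INFO tracks: %d individual track(s) from %d trip(s)",
      nrow(tracks_all), nrow(trips))
  tracks <- usable_tracks(tracks_all, constants)
  excluded <- attr(tracks, "excluded")
  if (nrow(excluded)) {
    for (i in seq_len(nrow(excluded))) {
      say("INFO excluded %s/%s: %s", excluded$station_id[i],
          excluded$hornet_id[i], excluded$reason[i])
    }
  }
  if (nrow(tracks) == 0) stop("no usable tracks")

  # optional nest-hypothesis grouping carried from the trips table
  hyp <- rep(NA_character_, nrow(tracks))
  if ("nest_hypothesis" %in% names(trips)) {
    key <- paste(trips$station_id, trips$hornet_id)
    hyp <- as.character(trips$nest_hypothesis[
      match(paste(tracks$station_id, tracks$hornet_id), key)])
  }

  regions <- lapply(seq_len(nrow(tracks)), function(i) {
    tr <- tracks[i, ]
    sxy <- unlist(station_xy[station_xy$station_id == tr$station_id, c("x", "y")])
    rg <- build_sector_annulus(sxy, tr, constants, arc_step = arc_step,
                               frame = frame)
    say("INFO region %s/%s: t_min %.0f s, band %.1f-%.1f m, bearing %.1f deg +/- %g deg, area %.0f m2",
        tr$station_id, tr$hornet_id, tr$t_min_s, rg$d_min_m, rg$d_max_m,
        rg$mean_bearing_deg, rg$half_angle_deg, rg$area_m2)
    rg
  })

  convergent <- list()
  n_st <- length(unique(tracks$station_id))
  if (n_st >= 2) {
    idx <- seq_along(regions)
    for (i in idx) for (j in idx[idx > i]) {
      if (tracks$station_id[i] == tracks$station_id[j]) next
      if (!is.na(hyp[i]) && !is.na(hyp[j]) && hyp[i] != hyp[j]) next
      cv <- intersect_regions(regions[c(i, j)])
      say("INFO convergence %s/%s x %s/%s: %s",
          tracks$station_id[i], tracks$hornet_id[i],
          tracks$station_id[j], tracks$hornet_id[j],
          if (is_empty_region(cv)) "no convergence"
          else sprintf("area %.0f m2", cv$area_m2))
      convergent[[length(convergent) + 1L]] <- cv
    }
    if (n_st >= 3) {
      best <- best_track_per_station(tracks)
      sel <- match(paste(best$station_id, best$hornet_id),
                   paste(tracks$station_id, tracks$hornet_id))
      convergent[[length(convergent) + 1L]] <- intersect_regions(regions[sel])
    }
  }

  suggestion <- NULL
  if (n_st == 1) {
    best <- best_track_per_station(tracks)
    sel <- match(paste(best$station_id, best$hornet_id),
                 paste(tracks$station_id, tracks$hornet_id))
    suggestion <- suggest_second_station(regions[[sel]], margin = margin)
    say("INFO single station: suggested second bait station at x=%.1f y=%.1f m",
        suggestion[["x"]], suggestion[["y"]])
  }

  structure(list(frame = frame, station_xy = station_xy, tracks = tracks,
                 excluded = excluded, regions = regions,
                 convergent = convergent, suggestion = suggestion,
                 constants = constants),
            class = "nest_search")
}

search_summary_lines <- function(res) {
  out <- character(0)
  add <- function(...) out <<- c(out, sprintf(...))
  add("Phase-1 nest search: %d usable track(s), %d excluded",
      nrow(res$tracks), nrow(res$excluded))
  for (i in seq_len(nrow(res$tracks))) {
    tr <- res$tracks[i, ]; rg <- res$regions[[i]]
    add("  %s/%s  n=%d  t_min=%.0f s  d=[%.1f, %.1f] m  bearing=%.1f deg +/-%g  area=%.0f m2",
        tr$station_id, tr$hornet_id, tr$n_trips, tr$t_min_s,
        rg$d_min_m, rg$d_max_m, rg$mean_bearing_deg, rg$half_angle_deg, rg$area_m2)
  }
  for (cv in res$convergent) {
    who <- paste(sprintf("%s/%s", cv$provenance$station_id,
                         cv$provenance$hornet_id), collapse = " x ")
    if (is_empty_region(cv)) {
      add("  convergent [%s]: no convergence (consider re-running with the wider half-angle)", who)
    } else {
      ctr <- region_centroid(cv)
      add("  convergent [%s]: area=%.0f m2, centroid x=%.1f y=%.1f m",
          who, cv$area_m2, ctr[["x"]], ctr[["y"]])
    }
  }
  if (!is.null(res$suggestion)) {
    add("  suggested second bait station: x=%.1f y=%.1f m",
        res$suggestion[["x"]], res$suggestion[["y"]])
    if (res$frame$mode == "geographic") {
      ll <- from_local_frame(res$suggestion[["x"]], res$suggestion[["y"]], res$frame)
      add("    (lat=%.6f lon=%.6f)", ll$lat, ll$lon)
    }
  }
  out
}

#' @export
print.nest_search <- function(x, ...) {
  cat(paste(search_summary_lines(x), collapse = "\n"), "\n")
  invisible(x)
}
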