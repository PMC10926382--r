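#' Read a bait-station table
#'
#' CSV with a header; `station_id` plus either `lat`/`lon` (geographic
#' mode, decimal degrees WGS84) or `x_m`/`y_m` (planar mode, metres).
#'
#' @param path Path to the CSV file.
#' @param crs_mode `"geographic"` or `"planar"`.
#' @return Data frame of validated stations.
#' @export
read_stations <- function(path, crs_mode = c("geographic", "planar")) {
  crs_mode <- match.arg(crs_mode)
  if (!file.exists(path)) stop("stations file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- if (crs_mode == "geographic") c("station_id", "lat", "lon")
          else c("station_id", "x_m", "y_m")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop(sprintf("stations file %s: missing column(s) %s (crs_mode=%s)",
                 path, paste(miss, collapse = ", "), crs_mode))
  }
  if (nrow(df) == 0) stop("stations file is empty: ", path)
  if (anyDuplicated(df$station_id)) {
    dup <- unique(df$station_id[duplicated(df$station_id)])
    stop("duplicate station id(s): ", paste(dup, collapse = ", "))
  }
  if (crs_mode == "geographic") {
    if (any(!is.finite(df$lat)) || any(!is.finite(df$lon)) ||
        any(abs(df$lat) > 90) || any(abs(df$lon) > 180)) {
      stop("station coordinates out of range: lat in [-90,90], lon in [-180,180]")
    }
  } else {
    if (any(!is.finite(df$x_m)) || any(!is.finite(df$y_m))) {
      stop("station x_m/y_m must be finite")
    }
  }
  df[need]
}

parse_iso8601 <- function(x) {
  x <- trimws(x)
  out <- as.POSIXct(x, tz = "UTC", format = "%Y-%m-%dT%H:%M:%OS")
  miss <- is.na(out)
  out[miss] <- as.POSIXct(x[miss], tz = "UTC", format = "%Y-%m-%d %H:%M:%OS")
  miss <- is.na(out)
  # bare time of day (field notebooks often record HH:MM:SS only)
  out[miss] <- as.POSIXct(paste("1970-01-01", x[miss]), tz = "UTC",
                          format = "%Y-%m-%d %H:%M:%OS")
  out
}

#' Read a trip-observation table
#'
#' CSV with a header; columns `station_id`, `hornet_id`, `bearing_deg`
#' and either `round_trip_s` (seconds) or the pair
#' `depart_time`/`return_time` (ISO-8601 timestamps, differenced to
#' seconds; timestamps are treated as local clock readings and only ever
#' differenced, never absolutized). Bearings are normalized to [0, 360).
#'
#' @param path Path to the CSV file.
#' @return Data frame of trip observations with `round_trip_s` filled in.
#' @export
read_trips <- function(path) {
  if (!file.exists(path)) stop("trips file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  base_need <- c("station_id", "hornet_id", "bearing_deg")
  miss <- setdiff(base_need, names(df))
  if (length(miss)) {
    stop(sprintf("trips file %s: missing column(s) %s",
                 path, paste(miss, collapse = ", ")))
  }
  has_sec <- "round_trip_s" %in% names(df)
  has_ts <- all(c("depart_time", "return_time") %in% names(df))
  if (has_sec == has_ts) {
    stop("trips file must have exactly one duration encoding: ",
         "either round_trip_s or depart_time + return_time")
  }
  if (nrow(df) == 0) stop("trips file is empty: ", path)
  lines <- seq_len(nrow(df)) + 1L  # data row i is file line i+1 (header)
  if (has_ts) {
    dep <- parse_iso8601(df$depart_time)
    ret <- parse_iso8601(df$return_time)
    bad <- is.na(dep) | is.na(ret)
    if (any(bad)) {
      stop("unparseable timestamp(s) at line(s): ",
           paste(lines[bad], collapse = ", "))
    }
    df$round_trip_s <- as.numeric(difftime(ret, dep, units = "secs"))
  }
  if (any(!is.finite(df$round_trip_s))) {
    stop("non-numeric round_trip_s at line(s): ",
         paste(lines[!is.finite(df$round_trip_s)], collapse = ", "))
  }
  bad <- df$round_trip_s <= 0
  if (any(bad)) {
    stop("non-positive round-trip duration (return before depart?) at line(s): ",
         paste(lines[bad], collapse = ", "))
  }
  if (any(!is.finite(df$bearing_deg))) {
    stop("non-numeric bearing_deg at line(s): ",
         paste(lines[!is.finite(df$bearing_deg)], collapse = ", "))
  }
  df$bearing_deg <- normalize_bearing(df$bearing_deg)
  out <- df[c(base_need, "round_trip_s",
              intersect("nest_hypothesis", names(df)))]
  out
}

region_properties <- function(region) {
  prov <- region$provenance
  list(
    kind = region$kind,
    station_id = paste(unique(prov$station_id), collapse = ","),
    hornet_id = paste(unique(prov$hornet_id), collapse = ","),
    t_min_s = region$t_min_s,
    d_min_m = region$d_min_m,
    d_max_m = region$d_max_m,
    mean_bearing_deg = region$mean_bearing_deg,
    half_angle_deg = region$half_angle_deg,
    area_m2 = region$area_m2
  )
}

close_ring <- function(m) rbind(m, m[1, , drop = FALSE])

region_geometry <- function(region, frame) {
  rings <- lapply(region$rings, function(ring) {
    if (!is.null(frame) && frame$mode == "geographic") {
      ll <- from_local_frame(ring$x, ring$y, frame)
      close_ring(cbind(ll$lon, ll$lat))
    } else {
      close_ring(cbind(ring$x, ring$y))
    }
  })
  if (length(rings) == 1) {
    list(type = "Polygon", coordinates = rings)
  } else {
    list(type = "MultiPolygon", coordinates = lapply(rings, list))
  }
}

#' Write likely regions to a GeoJSON FeatureCollection
#'
#' In geographic mode, polygon coordinates are WGS84 lon/lat (the planar
#' metre coordinates are echoed per feature in `properties$rings_xy_m`);
#' in planar mode the raw x/y metres are written and the frame is
#' described in the top-level `frame` member. Per-feature properties:
#' kind, station_id, hornet_id, t_min_s, d_min_m, d_max_m,
#' mean_bearing_deg, half_angle_deg, area_m2.
#'
#' @param regions Non-empty list of `likely_region` objects.
#' @param frame The [local_frame()] the regions live in.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_regions_geojson <- function(regions, frame, path) {
  if (!is.list(regions) || length(regions) == 0 ||
      !all(vapply(regions, inherits, logical(1), "likely_region"))) {
    stop("regions must be a non-empty list of likely_region objects")
  }
  features <- lapply(regions, function(rg) {
    props <- region_properties(rg)
    if (frame$mode == "geographic") {
      props$rings_xy_m <- lapply(rg$rings, function(ring) cbind(ring$x, ring$y))
    }
    list(type = "Feature",
         geometry = if (is_empty_region(rg)) NULL else region_geometry(rg, frame),
         properties = props)
  })
  fc <- list(type = "FeatureCollection", features = features)
  if (frame$mode == "planar") {
    fc$frame <- list(mode = "planar",
                     description = "local metric frame: x metres east, y metres north of frame origin")
  } else {
    fc$frame <- list(mode = "geographic",
                     origin_lat = frame$origin_lat, origin_lon = frame$origin_lon,
                     description = "coordinates are WGS84 lon/lat; rings_xy_m echo the azimuthal-equidistant local frame")
  }
  json <- jsonlite::toJSON(fc, auto_unbox = TRUE, digits = 10, null = "null",
                           na = "null")
  ok <- tryCatch({ writeLines(json, path); TRUE },
                 error = function(e) stop("failed to write GeoJSON to ", path,
                                          ": ", conditionMessage(e)))
  invisible(path)
}

#' Read a run-configuration file
#'
#' Flat `key = value` lines, `#`/`;` comments, with an optional
#' `[simulation]` section holding the synthetic-scenario parameters.
#' Values that parse as numbers are returned numeric.
#'
#' @param path Path to the config file.
#' @return A list of top-level settings, with any `[simulation]` keys under
#'   `$simulation`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("^[#;].*$", "", lines)        # full-line comments
  lines <- sub("\\s[#;].*$", "", lines)      # trailing comments need a space
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  section <- NULL
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    if (!grepl("=", ln, fixed = TRUE)) stop("malformed config line: ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    if (!is.na(num)) val <- num
    if (is.null(section)) out[[key]] <- val else out[[section]][[key]] <- val
  }
  out
}
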