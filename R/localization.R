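# Signed shoelace area of one ring (positive when counter-clockwise in the
# x-east / y-north plane).
ring_signed_area <- function(ring) {
  x <- ring$x; y <- ring$y
  0.5 * sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)
}

rings_area <- function(rings) {
  if (length(rings) == 0) return(0)
  abs(sum(vapply(rings, ring_signed_area, numeric(1))))
}

rings_centroid <- function(rings) {
  # area-weighted centroid over all rings (holes carry negative weight
  # through their signed area)
  cx <- 0; cy <- 0; a <- 0
  for (ring in rings) {
    x <- ring$x; y <- ring$y
    xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
    cr <- x * yn - xn * y
    a6 <- sum(cr) / 2
    if (abs(a6) < .Machine$double.eps) next
    cx <- cx + sum((x + xn) * cr) / 6
    cy <- cy + sum((y + yn) * cr) / 6
    a <- a + a6
  }
  if (a == 0) stop("cannot compute centroid of an empty region")
  c(x = cx / a, y = cy / a)
}

new_likely_region <- function(rings, kind, provenance, frame, tol,
                              d_min = NA_real_, d_max = NA_real_,
                              mean_bearing = NA_real_, half_angle = NA_real_,
                              t_min = NA_real_, anchor_xy = NULL,
                              axis_bearing = NA_real_, diagnostic = NULL) {
  structure(list(
    rings = rings, area_m2 = rings_area(rings), kind = kind,
    provenance = provenance, frame = frame, tol = tol,
    d_min_m = d_min, d_max_m = d_max, mean_bearing_deg = mean_bearing,
    half_angle_deg = half_angle, t_min_s = t_min,
    anchor_xy = anchor_xy, axis_bearing_deg = axis_bearing,
    diagnostic = diagnostic
  ), class = "likely_region")
}

#' @export
print.likely_region <- function(x, ...) {
  if (length(x$rings) == 0) {
    cat(sprintf("<likely_region> %s: EMPTY (%s)\n", x$kind,
                if (is.null(x$diagnostic)) "no area" else x$diagnostic))
    return(invisible(x))
  }
  cat(sprintf("<likely_region> %s, area %.0f m2 (%.2f ha), %d ring(s)\n",
              x$kind, x$area_m2, x$area_m2 / 1e4, length(x$rings)))
  if (!is.na(x$d_min_m)) {
    cat(sprintf("  distance band %.1f-%.1f m, bearing %.1f deg +/- %g deg\n",
                x$d_min_m, x$d_max_m, x$mean_bearing_deg, x$half_angle_deg))
  }
  cat("  from: ", paste(sprintf("%s/%s", x$provenance$station_id,
                                x$provenance$hornet_id), collapse = ", "), "\n")
  invisible(x)
}

is_empty_region <- function(region) length(region$rings) == 0

#' Build the likely area for one individual at one bait station
#'
#' The likely nest area of a usable track is the intersection of (i) the
#' annulus between `d_min` and `d_max` centred on the bait station and (ii)
#' the wedge of bearings within the selected half-angle of the individual's
#' mean vanishing direction. The curved boundaries are discretized at
#' `arc_step` degrees per vertex; at the default 1 degree the polygon area
#' is within ~0.01% of the closed form
#' `(2*half_angle/360) * pi * (d_max^2 - d_min^2)`.
#'
#' @param station_xy Numeric length-2 (x, y) of the bait station in the
#'   local frame, metres.
#' @param track One row of [aggregate_tracks()] output (must pass
#'   [check_track_usable()]).
#' @param constants A [model_constants()] object.
#' @param arc_step Maximum degrees of arc per polygon edge, in (0, 5].
#' @param frame The [local_frame()] the station coordinates live in.
#' @return A `likely_region` of kind `"single-track"` with counter-clockwise
#'   vertices, its area in m2, and the band/bearing metadata.
#' @export
build_sector_annulus <- function(station_xy, track,
                                 constants = model_constants(),
                                 arc_step = 1, frame = local_frame(mode = "planar")) {
  stopifnot(length(station_xy) == 2, all(is.finite(station_xy)))
  if (!(arc_step > 0 && arc_step <= 5)) stop("arc_step must be in (0, 5]")
  rep <- check_track_usable(track, constants)
  if (!rep$usable) {
    stop("track not usable: ", paste(rep$reasons, collapse = "; "))
  }
  band <- estimate_distance_band(track$t_min_s, constants)
  alpha <- select_half_angle(track$t_min_s, constants)
  b0 <- track$mean_bearing_deg
  n_seg <- max(2L, ceiling(2 * alpha / arc_step))
  theta <- seq(b0 - alpha, b0 + alpha, length.out = n_seg + 1) * pi / 180
  outer_x <- station_xy[1] + band$d_max_m * sin(theta)
  outer_y <- station_xy[2] + band$d_max_m * cos(theta)
  inner_x <- station_xy[1] + band$d_min_m * sin(rev(theta))
  inner_y <- station_xy[2] + band$d_min_m * cos(rev(theta))
  ring <- list(x = c(outer_x, inner_x), y = c(outer_y, inner_y))
  if (ring_signed_area(ring) < 0) {
    ring <- list(x = rev(ring$x), y = rev(ring$y))
  }
  # worst-case chord sagitta of the discretized outer arc
  tol <- band$d_max_m * (1 - cos((arc_step * pi / 180) / 2))
  new_likely_region(
    rings = list(ring), kind = "single-track",
    provenance = data.frame(station_id = as.character(track$station_id),
                            hornet_id = as.character(track$hornet_id),
                            stringsAsFactors = FALSE),
    frame = frame, tol = max(tol, 1e-9),
    d_min = band$d_min_m, d_max = band$d_max_m,
    mean_bearing = b0, half_angle = alpha, t_min = track$t_min_s,
    anchor_xy = c(station_xy[1], station_xy[2]), axis_bearing = b0
  )
}

#' Intersect likely regions into a convergent area
#'
#' The convergent area — the intersection of likely areas obtained from
#' different individuals/stations — is the final, smaller search region.
#' An empty intersection is a reported outcome (regions may simply not
#' converge, e.g. hornets from different nests), not an error.
#'
#' @param regions A list of two or more `likely_region` objects sharing one
#'   local frame.
#' @return A `likely_region` of kind `"convergent"`; empty (zero rings,
#'   area 0) with `diagnostic = "no convergence"` when the inputs are
#'   disjoint.
#' @export
intersect_regions <- function(regions) {
  if (!is.list(regions) || length(regions) < 2) {
    stop("need at least two regions to intersect")
  }
  if (!all(vapply(regions, inherits, logical(1), "likely_region"))) {
    stop("all inputs must be likely_region objects")
  }
  for (r in regions[-1]) {
    if (!same_frame(regions[[1]]$frame, r$frame)) {
      stop("regions are in different local frames; re-project to a common frame first")
    }
  }
  prov <- unique(do.call(rbind, lapply(regions, `[[`, "provenance")))
  rownames(prov) <- NULL
  tol <- max(vapply(regions, `[[`, numeric(1), "tol"))
  acc <- regions[[1]]$rings
  for (r in regions[-1]) {
    if (length(acc) == 0) break
    acc <- polyclip::polyclip(acc, r$rings, op = "intersection",
                              fillA = "evenodd", fillB = "evenodd")
  }
  anchor <- regions[[1]]$anchor_xy
  if (length(acc) == 0) {
    return(new_likely_region(list(), kind = "convergent", provenance = prov,
                             frame = regions[[1]]$frame, tol = tol,
                             anchor_xy = anchor, diagnostic = "no convergence"))
  }
  ctr <- rings_centroid(acc)
  axis <- if (!is.null(anchor) && any(ctr != anchor)) {
    planar_bearing(anchor[1], anchor[2], ctr[1], ctr[2])
  } else NA_real_
  new_likely_region(acc, kind = "convergent", provenance = prov,
                    frame = regions[[1]]$frame, tol = tol,
                    anchor_xy = anchor, axis_bearing = axis)
}

# Minimum distance from point p = c(x, y) to the boundary of a set of rings.
dist_point_rings <- function(p, rings) {
  dmin <- Inf
  for (ring in rings) {
    x1 <- ring$x; y1 <- ring$y
    x2 <- c(x1[-1], x1[1]); y2 <- c(y1[-1], y1[1])
    dx <- x2 - x1; dy <- y2 - y1
    len2 <- dx^2 + dy^2
    t <- ifelse(len2 > 0, ((p[1] - x1) * dx + (p[2] - y1) * dy) / len2, 0)
    t <- pmin(1, pmax(0, t))
    d2 <- (p[1] - (x1 + t * dx))^2 + (p[2] - (y1 + t * dy))^2
    dmin <- min(dmin, sqrt(min(d2)))
  }
  dmin
}

#' Is a point inside a likely region?
#'
#' Even-odd containment with a boundary tolerance equal to the region's
#' arc-discretization tolerance, so points on a discretized arc count as
#' inside.
#'
#' @param region A `likely_region`.
#' @param point Numeric length-2 (x, y), metres in the region's frame.
#' @return `TRUE` iff the point is inside or on the boundary.
#' @export
containment_check <- function(region, point) {
  stopifnot(inherits(region, "likely_region"), length(point) == 2)
  if (is_empty_region(region)) return(FALSE)
  hits <- vapply(region$rings, function(ring) {
    polyclip::pointinpolygon(list(x = point[1], y = point[2]), ring)
  }, numeric(1))
  if (any(hits == -1)) return(TRUE)          # exactly on a boundary
  inside <- sum(hits == 1) %% 2 == 1         # even-odd across rings
  if (inside) return(TRUE)
  dist_point_rings(point, region$rings) <= region$tol
}

#' Suggest where to place a second bait station
#'
#' When a single station leaves the likely area too large, a second protein
#' bait station should be placed near but outside that area (hornets tend
#' not to visit protein baits in the immediate vicinity of their nest).
#' The suggestion lies on the ray from the originating station through the
#' region, just beyond its far edge, at a distance between `margin` and
#' `2 * margin` from the boundary. Deterministic given its inputs.
#'
#' @param region A non-empty `likely_region`.
#' @param margin Minimum clearance from the region boundary, metres.
#' @return Named numeric (x, y) of the suggested station position.
#' @export
suggest_second_station <- function(region, margin = 50) {
  stopifnot(inherits(region, "likely_region"))
  if (is_empty_region(region)) stop("cannot place a station around an empty region")
  if (!is.numeric(margin) || margin <= 0) stop("margin must be > 0")
  anchor <- region$anchor_xy
  axis <- region$axis_bearing_deg
  if (is.null(anchor) || is.na(axis)) {
    anchor <- rings_centroid(region$rings)
    axis <- 0
  }
  u <- c(sin(axis * pi / 180), cos(axis * pi / 180))
  # all polygon vertices projected on the axis; beyond the max the ray has
  # left the region for good
  proj <- unlist(lapply(region$rings, function(ring) {
    (ring$x - anchor[1]) * u[1] + (ring$y - anchor[2]) * u[2]
  }))
  t0 <- max(proj)
  target <- 1.5 * margin
  f <- function(t) {
    dist_point_rings(anchor + t * u, region$rings) - target
  }
  t_star <- tryCatch(
    stats::uniroot(f, lower = t0, upper = t0 + 4 * margin,
                   extendInt = "upX", tol = 1e-6)$root,
    error = function(e) t0 + target
  )
  p <- anchor + t_star * u
  d <- dist_point_rings(p, region$rings)
  if (d < margin || d > 2 * margin) p <- anchor + (t0 + target) * u
  c(x = unname(p[1]), y = unname(p[2]))
}

#' Centroid of a likely region
#'
#' @param region A non-empty `likely_region`.
#' @return Named numeric (x, y), metres.
#' @export
region_centroid <- function(region) {
  stopifnot(inherits(region, "likely_region"))
  if (is_empty_region(region)) stop("empty region has no centroid")
  rings_centroid(region$rings)
}
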