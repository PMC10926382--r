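---
title: "Bearing-and-time triangulation of hornet nests: model and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bearing-and-time triangulation of hornet nests: model and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vespalocate)
```

## The estimation problem

A *Vespa velutina* worker provisioning its colony from a protein bait is a
central-place forager: it departs the bait roughly along the straight line
to its nest, spends a short, fairly constant time on the nest, and returns.
Two observables per marked individual — the compass bearing along which it
vanishes and the elapsed bait–nest–bait time — therefore carry information
about where the nest is. This package turns those observations into map
polygons.

The round-trip time `t_t` decomposes as

$$ t_t = \frac{d}{v_\text{out}} + t_n + \frac{d}{v_\text{back}}, $$

with `d` the bait–nest distance, `t_n` the time on the nest, and leg speeds
`v`. Using the *minimum* time over an individual's trips (at least three)
suppresses trips inflated by detours or loitering; bracketing the unknown
speed between `s_min` and `s_max` and assuming symmetric legs gives

$$ d_\text{min} = \frac{t_t - t_n}{2}\, s_\text{min}, \qquad
   d_\text{max} = \frac{t_t - t_n}{2}\, s_\text{max}. $$

The bearing is summarized by the circular (unit-vector resultant) mean of
the individual's vanishing bearings — an arithmetic mean of degree values
would fail across the 0/360 wrap (350° and 10° average to 180° instead of
0°). The likely area is the intersection of the `[d_min, d_max]` annulus
with the wedge of bearings within a half-angle of the mean direction.

## Parameters

| parameter | default | units | role |
|---|---|---|---|
| `t_nest` | 45 | s | time on the nest per visit, field-estimated from 20 trips |
| `s_min` | 1.8 | m/s | mean observed speed of loaded foragers (30 flights, SD 0.32) |
| `s_max` | 5.4 | m/s | literature maximum for homing hornets (harmonic radar) |
| `angle_short` | 10 | deg | sector half-angle when the minimum trip is < 10 min |
| `angle_long` | 15 | deg | half-angle otherwise: deviation grows with distance |
| `trip_time_threshold` | 600 | s | short/long regime boundary |
| `min_trips` | 3 | — | minimum trips before a track is used |

`s_max` is deliberately conservative: a faster assumed speed can only
enlarge `d_max`, and an enlarged search area never excludes the true nest.
The `s_min`/`s_max` bracket is the model's only uncertainty mechanism; no
variance is propagated for `t_nest`.

Two deliberate rule choices where the verbal protocol is silent:

* **Threshold tie.** A minimum time of exactly 10 minutes takes the wider
  15° angle — conservative for the same reason as `s_max`.
* **The angle is chosen from the minimum round-trip time** of the
  individual, not trip-by-trip, matching how the band itself is computed.

A trip with `t_min ≤ t_nest` is an error, not a zero-width band: a
non-positive flight time means a mistimed observation or a confused
identity, and a zero-radius annulus is geometrically degenerate.

## Geometry and numerics

All geometry runs in a local planar frame (x east, y north, metres).
Geographic input is projected with an azimuthal equidistant projection on a
sphere of mean Earth radius, centred by default on the station centroid:
distances from the origin are exact in that model, and at the method's
sub-3-km scale the residual distortion (including the sphere/ellipsoid
difference, below ~0.5%) is negligible against the 3× speed bracket.
Points farther than 50 km from the origin are rejected as likely
coordinate mix-ups. Bearings are assumed to be relative to **true north**;
magnetic-declination correction is the observer's responsibility.

Sector-annulus boundaries are discretized at `arc_step = 1°` per vertex by
default. The chord error of a 1° arc is about `1 − sin(θ)/θ ≈ 5·10⁻⁵` in
relative area — far below the 0.5% tolerance the tests enforce and many
orders below the speed-bracket uncertainty; `arc_step` is configurable up
to 5° for coarse runs. The polygon's recorded area is its shoelace value,
and `containment_check()` treats points within the chord sagitta of the
boundary as inside, so discretization never flips a containment verdict on
the arc itself.

Region intersection uses the Clipper polygon-clipping library (R package
`polyclip`) with even-odd filling; intersection is associative and
commutative at the point-set level, so the order in which fully-formed
sector-annuli are intersected does not matter. An empty intersection is a
*reported outcome* (`diagnostic = "no convergence"`), with the suggested
remedy of re-running with the wide half-angle on all tracks — field data
will produce it, e.g. when two individuals come from different nests.

When more than one individual is usable per station, cross-station
intersections are computed pairwise for every pair of tracks from
*different* stations; tracks at the same station are never intersected with
each other, because they may belong to different colonies. An optional
`nest_hypothesis` column in the trips table restricts intersections to
tracks the user assigns to the same putative nest. Where one track per
station must be chosen (the full multi-station intersection, and the
recovery experiment), the track with the smallest circular bearing
dispersion is used — the computational analogue of focusing on "one
individual with consistent measurements" — with ties broken by id order.

The second-station suggestion is placed on the ray from the originating
station through the likely area, just beyond its far edge, at 1.5× the
requested margin from the boundary (clamped to `[margin, 2·margin]`), and
is fully deterministic. Placement *outside* the area reflects the observed
reluctance of hornets to visit protein baits very near their nest.

## What the simulator emulates — and what it does not

`simulate_trips()` draws, per trip, independent outbound and return speeds
from a truncated normal on `[1.8, 5.4]` m/s with mean 2.7 m/s (the maximum
speed estimated in the field, taken as a central loaded-flight value
between the bracketing constants) and SD 0.5; a nest-handling time from a
truncated normal 45 ± 10 s floored at 5 s (only the 45 s mean is reported
from the field, so the spread is a modelling choice); and a vanishing
bearing equal to the true station→nest bearing plus Gaussian noise with SD
3°, chosen so the 10° half-angle covers about 3σ. Output rows are shuffled
deterministically by the scenario seed to emulate interleaved observation;
replicate *r* of an experiment reuses the scenario with seed `seed + r`.

The simulator deliberately omits: flight-path tortuosity (times map to
straight-line distance), wind and weather effects (the protocol avoids
measuring in them), bait avoidance near the nest, vertical structure, and
multi-nest interference at one bait beyond per-individual identity. A
passing recovery experiment therefore shows that the *pipeline* inverts its
own generative model under field-calibrated noise — it does not certify
performance on real landscapes, where deviations from straight-line flight
bias distances upward (conservatively, toward larger `d`).

Validation problem sizes, chosen to keep the full suite desk-scale: the
recovery experiment uses 2 stations × 2 hornets × 5 trips over 200
replicates (the noise-free limit over 10–20), the Monte-Carlo area oracle
uses 10⁵ classified points against a 3-standard-error band, and the
closed-form area oracle is evaluated over a 20-point grid of
`(t_min, half_angle)` configurations at 1° discretization.

## Known limitations

* Strictly 2-D: a nest 22 m up a eucalypt projects onto the same map
  point; the polygon bounds horizontal position only.
* One nest per intersection group is assumed; intersecting regions of
  individuals from different nests silently produces a meaningless (often
  empty) area — the `nest_hypothesis` column exists for exactly this.
* `t_nest` enters as a constant; individuals with unusually long on-nest
  handling shift the band outward.
* The figshare field dataset accompanying the original study is not
  redistributed here; its columns can be mapped onto the
  `station_id,hornet_id,bearing_deg,round_trip_s` schema by the user.
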