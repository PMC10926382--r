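# Shared fixtures, generated in code.

# Two bait stations triangulating a nest 400 m north of BS1; BS2 sits to the
# east, near but outside BS1's likely area, as the field protocol advises.
default_stations <- function() {
  data.frame(station_id = c("BS1", "BS2"), x = c(0, 300), y = c(0, 100),
             stringsAsFactors = FALSE)
}

default_scenario <- function(seed = 1, ...) {
  simulation_scenario(true_nest = c(0, 400), stations = default_stations(),
                      seed = seed, ...)
}

noise_free_scenario <- function(seed = 1) {
  default_scenario(seed = seed, speed_sd = 0, handling_sd = 0,
                   bearing_noise_sd = 0, handling_mean = 45)
}

# One usable individual track row, in aggregate_tracks() output shape.
make_track <- function(station_id = "BS1", hornet_id = "H01", n_trips = 3,
                       t_min_s = 345, mean_bearing_deg = 0,
                       bearing_dispersion_deg = 2) {
  data.frame(station_id = station_id, hornet_id = hornet_id,
             n_trips = n_trips, t_min_s = t_min_s,
             mean_bearing_deg = mean_bearing_deg,
             bearing_dispersion_deg = bearing_dispersion_deg,
             stringsAsFactors = FALSE)
}

# Smallest absolute difference between two bearings, degrees.
angdiff <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

# Write a simulated dataset to CSVs under dir; returns the paths.
write_sim_fixture <- function(dir, scenario = default_scenario(seed = 11)) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  trips <- simulate_trips(scenario)
  st <- scenario$stations
  stations_path <- file.path(dir, "stations.csv")
  trips_path <- file.path(dir, "trips.csv")
  utils::write.csv(data.frame(station_id = st$station_id,
                              x_m = st$x, y_m = st$y),
                   stations_path, row.names = FALSE, quote = FALSE)
  utils::write.csv(trips, trips_path, row.names = FALSE, quote = FALSE)
  list(stations = stations_path, trips = trips_path,
       nest = unname(scenario$true_nest))
}

sim_config_text <- function(seed = 11, n_hornets = 1, trips = 5,
                            extra = character(0)) {
  c("# synthetic scenario",
    "[simulation]",
    "stations = BS1:0:0;BS2:300:100",
    "nest_x = 0", "nest_y = 400",
    sprintf("n_hornets_per_station = %d", n_hornets),
    sprintf("trips_per_hornet = %d", trips),
    sprintf("seed = %d", seed),
    extra)
}
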