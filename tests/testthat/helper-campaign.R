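# Shared fixtures: scaled-down campaign configurations and independent
# brute-force oracles for the energy-based sound metrics.

small_config <- function(seed = 1, ...) {
  defaults <- list(
    n_fixed = 2, n_rotating = 6,
    seasons = list(
      dry = list(start = "2023-01-18", end = "2023-01-31"),
      wet = list(start = "2023-07-22", end = "2023-08-04")
    ),
    seed = seed
  )
  do.call(campaign_config, utils::modifyList(defaults, list(...)))
}

# All stochastic elements switched off: constant exposure at the
# configured expectation, unbiased noise-free sensors, exact filters.
deterministic_config <- function(seed = 1, ...) {
  defaults <- list(
    seed = seed,
    weekly_trend = c(dry = 1, wet = 1),
    diurnal_night_day = c(dry = 1, wet = 1),
    sigma_site = 0, sigma_minute = 0,
    sensor_bias = c(dry = 1, wet = 1), sensor_noise_sd = 0,
    weighing_sd = 0, atn_noise_sd = 0,
    failure_prob = 0,
    sound_site_sd = 0, sound_noise_sd = 0,
    sound_day_offset = 0, sound_night_offset = 0,
    event_times = character()
  )
  do.call(small_config, utils::modifyList(defaults, list(...)))
}

# Brute-force oracles: explicit per-minute energy sums, independent of
# the vectorised implementations.
laeq_brute <- function(values) {
  total <- 0
  for (v in values) total <- total + 10^(v / 10)
  10 * log10(total / length(values))
}

ir_brute <- function(values, k) {
  ref <- laeq_brute(values) + k
  ev <- 0; total <- 0
  for (v in values) {
    e <- 10^(v / 10)
    total <- total + e
    if (v >= ref) ev <- ev + e
  }
  100 * ev / total
}

minute_tibble <- function(values, start = "2023-01-18 00:00:00",
                          deployment_id = "D0001", site_id = "S001",
                          season = "dry") {
  tibble::tibble(
    deployment_id = deployment_id, site_id = site_id, season = season,
    timestamp = as.POSIXct(start, tz = "UTC") + 60 * (seq_along(values) - 1),
    quantity = "sound_dba", value = values
  )
}
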