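test_that("site network respects counts, categories and seeding", {
  cfg <- campaign_config(n_fixed = 8, n_rotating = 62, seed = 5)
  sites <- generate_site_network(cfg)
  expect_equal(nrow(sites), 70)
  expect_equal(sum(sites$site_class == "fixed"), 8)
  expect_true(all(sites$land_use %in%
                    c("residential", "commercial_industrial", "gbo",
                      "transportation", "mixed_use")))
  expect_false(any(duplicated(sites$site_id)))
  expect_equal(sum(sites$high_range_flag), 1)
  expect_identical(sites, generate_site_network(cfg))

  mono <- small_config(land_use_proportions = c(residential = 1),
                       land_use_multipliers = c(residential = 1))
  expect_true(all(generate_site_network(mono)$land_use == "residential"))
})

test_that("configuration invariants are enforced", {
  expect_error(campaign_config(n_fixed = 0), class = "airsound_error_config")
  expect_error(campaign_config(failure_prob = 1.2),
               class = "airsound_error_config")
  expect_error(campaign_config(dry_wet_ratio = -1),
               class = "airsound_error_config")
  expect_error(
    campaign_config(seasons = list(
      dry = list(start = "2023-01-01", end = "2023-06-30"),
      wet = list(start = "2023-06-01", end = "2023-09-01"))),
    class = "airsound_error_config")
})

test_that("noise-free exposure series sit exactly at the configured level", {
  cfg <- deterministic_config()
  sites <- generate_site_network(cfg)
  dep <- simulate_deployment_schedule(sites, cfg)
  true <- simulate_true_pm(sites, cfg, dep)
  expected <- expected_site_mean(sites, "dry", cfg, conditional = TRUE)
  names(expected) <- sites$site_id
  dry <- true[true$season == "dry", ]
  by_site <- tapply(dry$value, dry$site_id, mean)
  expect_equal(as.numeric(by_site),
               as.numeric(expected[names(by_site)]), tolerance = 1e-12)
})

test_that("realized dry/wet contrast converges to the configured ratio", {
  cfg <- small_config(n_fixed = 1, n_rotating = 0, sigma_site = 0,
                      failure_prob = 0)
  sites <- generate_site_network(cfg)
  true <- simulate_true_pm(sites, cfg) # full-season series, >= 20k min/season
  means <- tapply(true$value, true$season, mean)
  expect_equal(unname(means["dry"] / means["wet"]), cfg$dry_wet_ratio,
               tolerance = 0.05)
  expect_true(all(true$value >= 0))
})

test_that("high-range flag scales the seasonal mean by its multiplier", {
  cfg <- deterministic_config(high_range_multiplier = 3.6)
  sites <- generate_site_network(cfg)
  hr <- sites[sites$high_range_flag, ]
  ref <- sites[!sites$high_range_flag &
                 sites$land_use == hr$land_use[1], ][1, ]
  expect_equal(expected_site_mean(hr, "dry", cfg),
               3.6 * expected_site_mean(ref, "dry", cfg))
})

test_that("sensor stream applies seasonal bias with zero-mean noise", {
  cfg <- deterministic_config()
  sites <- generate_site_network(cfg)
  dep <- simulate_deployment_schedule(sites, cfg)
  true <- simulate_true_pm(sites, cfg, dep)

  raw_id <- simulate_sensor_stream(true, cfg)
  expect_equal(raw_id$value, true$value)
  expect_true(all(raw_id$quantity == "pm_sensor_raw"))

  cfg2 <- deterministic_config(sensor_bias = c(dry = 0.64, wet = 0.64))
  raw_b <- simulate_sensor_stream(true, cfg2)
  expect_equal(raw_b$value, 0.64 * true$value, tolerance = 1e-12)

  cfg3 <- deterministic_config(sensor_bias = c(dry = 0.64, wet = 0.64),
                               sensor_noise_sd = 5)
  raw_n <- simulate_sensor_stream(true, cfg3)
  expect_equal(mean(raw_n$value) / mean(true$value), 0.64, tolerance = 0.02)
})

test_that("simulated filters follow the duty-cycled mass balance", {
  cfg <- deterministic_config()
  dep <- tibble::tibble(deployment_id = "D1", site_id = "S1",
                        season = "dry", achieved_minutes = 1440L)
  true <- minute_tibble(rep(100, 1440))
  f <- simulate_filter_sample(true, dep, cfg)
  delta <- mean(c(f$post_mass_1, f$post_mass_2, f$post_mass_3)) -
    mean(c(f$pre_mass_1, f$pre_mass_2, f$pre_mass_3))
  # 100 ug/m3 * 0.72 m3 + 2 ug dry blank offset
  expect_equal(delta, 74, tolerance = 1e-9)

  blank <- simulate_filter_sample(NULL, dep, cfg, is_blank = TRUE)
  bdelta <- mean(c(blank$post_mass_1, blank$post_mass_2, blank$post_mass_3)) -
    mean(c(blank$pre_mass_1, blank$pre_mass_2, blank$pre_mass_3))
  expect_equal(bdelta, cfg$mass_blank[["dry"]], tolerance = 1e-9)
})

test_that("filter generation is reproducible under a fixed seed", {
  cfg <- small_config(seed = 11)
  sites <- generate_site_network(cfg)
  dep <- simulate_deployment_schedule(sites, cfg)
  true <- simulate_true_pm(sites, cfg, dep)
  f1 <- simulate_filter_samples(true, dep, cfg)
  f2 <- simulate_filter_samples(true, dep, cfg)
  expect_identical(f1, f2)
  expect_true(any(f1$is_blank))
})

test_that("sound generator reproduces background, events and ordering", {
  cfg <- deterministic_config(
    land_use_proportions = c(residential = 1),
    land_use_multipliers = c(residential = 1),
    high_range_multiplier = 1)
  sites <- generate_site_network(cfg)
  dep <- simulate_deployment_schedule(sites, cfg)
  snd <- simulate_sound_stream(sites, cfg, dep)
  expect_true(all(snd$value == cfg$sound_background[["residential"]]))

  cfg_ev <- deterministic_config(
    land_use_proportions = c(residential = 1),
    land_use_multipliers = c(residential = 1),
    high_range_multiplier = 1,
    event_times = "05:00", event_minutes = 1L, event_boost = 15)
  snd_ev <- simulate_sound_stream(sites, cfg_ev, dep)
  mod <- as.POSIXlt(snd_ev$timestamp, tz = "UTC")
  at_5 <- mod$hour == 5 & mod$min == 0
  before <- mod$hour == 4 & mod$min == 59
  expect_equal(unique(snd_ev$value[at_5] - snd_ev$value[before][1]), 15)

  # residential < mixed_use medians on long series under the defaults
  cfg_mix <- small_config(n_fixed = 2, n_rotating = 0,
                          land_use_proportions = c(residential = 0.5,
                                                   mixed_use = 0.5),
                          high_range_multiplier = 1)
  sites_m <- generate_site_network(cfg_mix)
  dep_m <- simulate_deployment_schedule(sites_m, cfg_mix)
  snd_m <- simulate_sound_stream(sites_m, cfg_mix, dep_m)
  med <- tapply(snd_m$value, sites_m$land_use[match(snd_m$site_id,
                                                    sites_m$site_id)], median)
  expect_lt(med[["residential"]], med[["mixed_use"]])
  expect_true(all(snd_m$value >= cfg_mix$sound_bounds[1] &
                    snd_m$value <= cfg_mix$sound_bounds[2]))
})

test_that("deployment schedule covers seasons and models battery failure", {
  cfg0 <- small_config(failure_prob = 0)
  sites <- generate_site_network(cfg0)
  dep0 <- simulate_deployment_schedule(sites, cfg0)
  expect_true(all(dep0$achieved_minutes == dep0$planned_minutes))
  expect_true(all(dep0$achieved_minutes <= dep0$planned_minutes))

  # fixed sites tile the season in consecutive replacement cycles
  fixed1 <- dep0[dep0$site_id == sites$site_id[sites$site_class == "fixed"][1] &
                   dep0$season == "dry", ]
  fixed1 <- fixed1[order(fixed1$start), ]
  gaps <- diff(as.numeric(fixed1$start)) / 60
  expect_equal(gaps, fixed1$planned_minutes[-nrow(fixed1)])

  cfg1 <- small_config(failure_prob = 1)
  dep1 <- simulate_deployment_schedule(sites, cfg1)
  expect_true(all(dep1$achieved_minutes < dep1$planned_minutes))

  # rotating starts staggered across the season's full week range
  cfg_wide <- campaign_config(
    n_fixed = 1, n_rotating = 20,
    seasons = list(dry = list(start = "2023-01-18", end = "2023-03-17"),
                   wet = list(start = "2023-07-22", end = "2023-09-24")),
    failure_prob = 0, seed = 3)
  sites_w <- generate_site_network(cfg_wide)
  dep_w <- simulate_deployment_schedule(sites_w, cfg_wide)
  rot_dry <- dep_w[dep_w$season == "dry" &
                     dep_w$site_id %in%
                       sites_w$site_id[sites_w$site_class == "rotating"], ]
  wk <- week_index(rot_dry$start, as.Date("2023-01-18"))
  expect_equal(min(wk), 1)
  expect_gte(max(wk), 8)
})
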