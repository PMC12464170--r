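LAND_USE_LEVELS <- c(
  "residential", "commercial_industrial", "gbo", "transportation",
  "mixed_use"
)

SEASONS <- c("dry", "wet")

#' Campaign configuration
#'
#' Builds the configuration object that drives the synthetic campaign
#' generator and supplies shared constants to the downstream stages. The
#' defaults describe a two-season Dhaka-style campaign: 8 fixed and 62
#' rotating sites, a dry season (mid-January to mid-March) with roughly
#' four times the PM2.5 of the wet season (late July to late September),
#' a declining within-season weekly trend in the dry season, nocturnal
#' PM2.5 elevation in the dry season, land-use-dependent site levels,
#' sensor underestimation of 36% (dry) and 2% (wet), field-blank offsets,
#' prayer-call sound peaks, and an 11% battery-failure rate.
#'
#' @param n_fixed,n_rotating Number of fixed and rotating sites.
#' @param seasons Named list of `list(start, end)` Date windows for the
#'   `dry` and `wet` seasons; windows must be disjoint.
#' @param wet_mean Wet-season seasonal-mean PM2.5 (ug/m3) at a
#'   multiplier-1 site; the dry-season base is `wet_mean * dry_wet_ratio`.
#' @param dry_wet_ratio Dry/wet seasonal PM2.5 contrast (default 4).
#' @param weekly_trend Named multiplicative slope per week for each season
#'   (e.g. 0.93 means each week averages 7% lower than the last).
#' @param diurnal_night_day Named night/day mean PM2.5 ratio per season.
#' @param land_use_multipliers Named positive multipliers on the seasonal
#'   base level, one per land-use category.
#' @param land_use_proportions Target share of sites per land-use category.
#' @param high_range_multiplier Extra multiplier for the single
#'   heavy-industry ("high range") fixed site, when configured.
#' @param sigma_site Log-scale SD of the lognormal between-site random
#'   effect (mean-corrected so E\[effect\] = 1).
#' @param sigma_minute Log-scale SD of minute-level lognormal noise.
#' @param sensor_bias Named multiplicative sensor bias per season (defaults
#'   0.64 dry, 0.98 wet: the sensor underestimates).
#' @param sensor_noise_sd Additive sensor noise SD (ug/m3).
#' @param mass_blank,atn_blank Named per-season field-blank medians for
#'   filter mass (ug) and optical attenuation (ATN units).
#' @param bc_fraction Named per-season BC/PM2.5 mass fraction used when
#'   simulating filter attenuation.
#' @param flow_rate,duty_cycle Pump flow (L/min) and duty cycle used by the
#'   simulated gravimetric samplers.
#' @param tare_mass Nominal unexposed filter mass (ug).
#' @param weighing_sd Within-triplicate weighing noise SD (ug).
#' @param atn_noise_sd Attenuation measurement noise SD (ATN units).
#' @param blank_frac Fraction of deployments that also carry a field blank.
#' @param sound_background Named background level (dBA) per land use.
#' @param sound_day_offset,sound_night_offset Additive day/night offsets
#'   (dBA) applied to the background.
#' @param sound_site_sd Between-site SD of the sound background (dBA).
#' @param sound_noise_sd Minute-level sound noise SD (dBA).
#' @param event_times Character clock times ("HH:MM") of daily broadcast
#'   events (calls to prayer).
#' @param event_boost Event level boost (dBA).
#' @param event_minutes Duration of each event (minutes).
#' @param sound_bounds Length-2 numeric, allowed dBA range.
#' @param failure_prob Per-deployment battery-failure probability.
#' @param fixed_cycle_days Fixed-site monitor replacement cycle (days).
#' @param rotating_days Rotating deployment length (days).
#' @param completeness Fraction of a 1440-minute block that must be
#'   observed for the measurement-day to be retained.
#' @param seed Integer seed; the whole campaign is reproducible from it.
#' @return A list of class `campaign_config`.
#' @export
campaign_config <- function(n_fixed = 8L,
                            n_rotating = 62L,
                            seasons = list(
                              dry = list(start = as.Date("2023-01-18"),
                                         end = as.Date("2023-03-17")),
                              wet = list(start = as.Date("2023-07-22"),
                                         end = as.Date("2023-09-24"))
                            ),
                            wet_mean = 50,
                            dry_wet_ratio = 4,
                            weekly_trend = c(dry = 0.93, wet = 1.02),
                            diurnal_night_day = c(dry = 1.20, wet = 1.07),
                            land_use_multipliers = c(
                              residential = 0.92,
                              commercial_industrial = 1.10,
                              gbo = 0.90,
                              transportation = 1.04,
                              mixed_use = 0.94
                            ),
                            land_use_proportions = c(
                              residential = 19 / 70,
                              commercial_industrial = 16 / 70,
                              gbo = 8 / 70,
                              transportation = 18 / 70,
                              mixed_use = 9 / 70
                            ),
                            high_range_multiplier = 3.6,
                            sigma_site = 0.15,
                            sigma_minute = 0.35,
                            sensor_bias = c(dry = 0.64, wet = 0.98),
                            sensor_noise_sd = 5,
                            mass_blank = c(dry = 2, wet = 4),
                            atn_blank = c(dry = 2.03, wet = 0.15),
                            bc_fraction = c(dry = 0.070, wet = 0.054),
                            flow_rate = 1.0,
                            duty_cycle = 0.5,
                            tare_mass = 146000,
                            weighing_sd = 0.5,
                            atn_noise_sd = 0.1,
                            blank_frac = 0.16,
                            sound_background = c(
                              residential = 61,
                              commercial_industrial = 65,
                              gbo = 55,
                              transportation = 70,
                              mixed_use = 73
                            ),
                            sound_day_offset = 1.8,
                            sound_night_offset = -3.0,
                            sound_site_sd = 1.5,
                            sound_noise_sd = 4,
                            event_times = c("05:00", "13:15", "16:45",
                                            "18:15", "19:45"),
                            event_boost = 12,
                            event_minutes = 5L,
                            sound_bounds = c(25, 130),
                            failure_prob = 0.11,
                            fixed_cycle_days = 5L,
                            rotating_days = 3L,
                            completeness = 0.8,
                            seed = 1L) {
  config <- list(
    n_fixed = as.integer(n_fixed), n_rotating = as.integer(n_rotating),
    seasons = lapply(seasons, function(s)
      list(start = as.Date(s$start), end = as.Date(s$end))),
    wet_mean = wet_mean, dry_wet_ratio = dry_wet_ratio,
    weekly_trend = weekly_trend, diurnal_night_day = diurnal_night_day,
    land_use_multipliers = land_use_multipliers,
    land_use_proportions = land_use_proportions,
    high_range_multiplier = high_range_multiplier,
    sigma_site = sigma_site, sigma_minute = sigma_minute,
    sensor_bias = sensor_bias, sensor_noise_sd = sensor_noise_sd,
    mass_blank = mass_blank, atn_blank = atn_blank,
    bc_fraction = bc_fraction,
    flow_rate = flow_rate, duty_cycle = duty_cycle,
    tare_mass = tare_mass, weighing_sd = weighing_sd,
    atn_noise_sd = atn_noise_sd, blank_frac = blank_frac,
    sound_background = sound_background,
    sound_day_offset = sound_day_offset,
    sound_night_offset = sound_night_offset,
    sound_site_sd = sound_site_sd, sound_noise_sd = sound_noise_sd,
    event_times = event_times, event_boost = event_boost,
    event_minutes = as.integer(event_minutes),
    sound_bounds = sound_bounds,
    failure_prob = failure_prob,
    fixed_cycle_days = as.integer(fixed_cycle_days),
    rotating_days = as.integer(rotating_days),
    completeness = completeness,
    seed = as.integer(seed)
  )
  class(config) <- "campaign_config"
  validate_config(config)
  config
}

validate_config <- function(config) {
  stop_config <- function(msg) {
    abort(msg, class = "airsound_error_config")
  }
  if (config$n_fixed < 1L) stop_config("n_fixed must be >= 1")
  if (config$n_rotating < 0L) stop_config("n_rotating must be >= 0")
  if (!setequal(names(config$seasons), SEASONS))
    stop_config("seasons must name exactly 'dry' and 'wet' windows")
  dry <- config$seasons$dry; wet <- config$seasons$wet
  for (s in list(dry, wet)) {
    if (s$end < s$start) stop_config("season window end precedes start")
  }
  if (dry$start <= wet$end && wet$start <= dry$end)
    stop_config("season windows must be disjoint")
  pos <- c(config$wet_mean, config$dry_wet_ratio, config$weekly_trend,
           config$diurnal_night_day, config$land_use_multipliers,
           config$high_range_multiplier, config$sensor_bias,
           config$flow_rate)
  if (any(!is.finite(pos)) || any(pos <= 0))
    stop_config("multipliers, ratios, biases and flow must be strictly positive")
  if (config$failure_prob < 0 || config$failure_prob > 1)
    stop_config("failure_prob must lie in [0, 1]")
  if (config$duty_cycle <= 0 || config$duty_cycle > 1)
    stop_config("duty_cycle must lie in (0, 1]")
  miss <- setdiff(names(config$land_use_multipliers), LAND_USE_LEVELS)
  if (length(miss))
    stop_config(paste("unknown land_use categories:", paste(miss, collapse = ", ")))
  invisible(config)
}

season_days <- function(config, season) {
  s <- config$seasons[[season]]
  seq(s$start, s$end, by = "day")
}

# Duration-weighted normalisation of the weekly trend so that the
# season-long mean of the trend factor is exactly 1; the seasonal base
# level is then the expected seasonal mean.
trend_factor <- function(config, season, weeks) {
  r <- config$weekly_trend[[season]]
  days <- season_days(config, season)
  w <- week_index(days, config$seasons[[season]]$start)
  norm <- mean(r^(w - 1))
  r^(weeks - 1) / norm
}

# Day/night multiplicative diurnal factors, normalised so the
# duration-weighted daily mean is 1 (900 day minutes, 540 night minutes).
diurnal_factors <- function(config, season) {
  a <- config$diurnal_night_day[[season]]
  day <- MINUTES_PER_DAY / (DAY_WINDOW_MINUTES + NIGHT_WINDOW_MINUTES * a)
  c(day = day, night = a * day)
}

season_base <- function(config, season) {
  if (season == "wet") config$wet_mean else config$wet_mean * config$dry_wet_ratio
}

#' Expected seasonal-mean PM2.5 for a site
#'
#' The generator's own expectation: seasonal base level times the site's
#' land-use multiplier and, for the high-range site, the heavy-industry
#' multiplier. The lognormal site effect and minute noise are
#' mean-corrected, so this is the exact expectation of the season-long
#' mean (averaging over site effects); multiply by `site_factor` for the
#' conditional expectation of a realised site.
#'
#' @param sites Site table from [generate_site_network()].
#' @param season `"dry"` or `"wet"`.
#' @param config A [campaign_config()].
#' @param conditional If `TRUE`, include the realised `site_factor`.
#' @return Numeric vector of expected means (ug/m3), one per site row.
#' @export
expected_site_mean <- function(sites, season, config, conditional = FALSE) {
  base <- season_base(config, season)
  mult <- config$land_use_multipliers[sites$land_use]
  hr <- ifelse(sites$high_range_flag, config$high_range_multiplier, 1)
  out <- base * unname(mult) * hr
  if (conditional) out <- out * sites$site_factor
  out
}

# Deterministic sub-seeds per generator stage, kept below 2^31.
stage_seed <- function(config, stage) {
  offsets <- c(sites = 11L, schedule = 23L, pm = 37L, sensor = 53L,
               filters = 71L, sound = 89L)
  (config$seed * 1000L + offsets[[stage]]) %% 2147483629L
}
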