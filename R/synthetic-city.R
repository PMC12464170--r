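# Synthetic campaign generator. The exposure model is multiplicative
# lognormal: true PM2.5 at minute t of a site is
#   base(season) * land_use_mult * high_range_mult * site_factor
#     * trend(week of t) * diurnal(day/night) * exp(noise)
# with the site factor, trend and diurnal factor normalised so the
# expected seasonal mean equals expected_site_mean().

#' Generate the site network
#'
#' Creates the configured number of fixed and rotating sites, allocates
#' land-use categories to approximate the configured proportions (largest
#' remainder method), draws the lognormal between-site effect, and flags
#' one fixed commercial/industrial site as the heavy-industry high-range
#' site when `high_range_multiplier > 1`.
#'
#' @param config A [campaign_config()].
#' @return A tibble with columns `site_id`, `site_class`, `land_use`,
#'   `x`, `y` (abstract km coordinates), `high_range_flag`,
#'   `site_factor` (latent multiplicative site effect).
#' @export
generate_site_network <- function(config) {
  set.seed(stage_seed(config, "sites"))
  n <- config$n_fixed + config$n_rotating
  land_use <- allocate_land_use(n, config$land_use_proportions)
  land_use <- sample(land_use)

  site_class <- c(rep("fixed", config$n_fixed),
                  rep("rotating", config$n_rotating))
  site_id <- sprintf("S%03d", seq_len(n))

  high_range <- rep(FALSE, n)
  if (config$high_range_multiplier > 1) {
    fixed_idx <- which(site_class == "fixed")
    # prefer a fixed commercial/industrial site; keep its category as-is
    ci_fixed <- fixed_idx[land_use[fixed_idx] == "commercial_industrial"]
    target <- if (length(ci_fixed)) ci_fixed[1] else fixed_idx[1]
    high_range[target] <- TRUE
  }

  site_factor <- exp(rnorm(n, -config$sigma_site^2 / 2, config$sigma_site))

  tibble::tibble(
    site_id = site_id,
    site_class = site_class,
    land_use = land_use,
    x = runif(n, 0, 20),
    y = runif(n, 0, 25),
    high_range_flag = high_range,
    site_factor = site_factor
  )
}

allocate_land_use <- function(n, props) {
  props <- props / sum(props)
  counts <- floor(n * props)
  rem <- n - sum(counts)
  if (rem > 0) {
    frac <- n * props - counts
    bump <- order(frac, decreasing = TRUE)[seq_len(rem)]
    counts[bump] <- counts[bump] + 1
  }
  rep(names(props), times = counts)
}

#' Simulate the deployment schedule
#'
#' Fixed sites are covered continuously in monitor-replacement cycles
#' (default 5 days) over each season; each rotating site receives one
#' 3-day deployment per season, with start weeks staggered across the
#' season's full week range. With probability `failure_prob` a
#' deployment's battery fails and its record is truncated at a uniform
#' random point in the final 40% of the planned duration. Fixed sites
#' carry PM sensors, gravimetric samplers and sound meters in both
#' seasons; rotating sites carry sound meters in the wet season only.
#'
#' @param sites Site table from [generate_site_network()].
#' @param config A [campaign_config()].
#' @return A tibble with one row per deployment: `deployment_id`,
#'   `site_id`, `season`, `start` (POSIXct), `planned_minutes`,
#'   `achieved_minutes`, `has_pm_sensor`, `has_gravimetric`, `has_sound`.
#' @export
simulate_deployment_schedule <- function(sites, config) {
  set.seed(stage_seed(config, "schedule"))
  rows <- list()
  for (season in SEASONS) {
    win <- config$seasons[[season]]
    n_days <- as.integer(win$end - win$start) + 1L
    season_end <- as_naive_posix(win$start) + n_days * 86400

    for (i in which(sites$site_class == "fixed")) {
      cycle_min <- config$fixed_cycle_days * MINUTES_PER_DAY
      start <- as_naive_posix(win$start)
      while (start < season_end) {
        planned <- min(cycle_min, as.numeric(difftime(season_end, start, units = "mins")))
        rows[[length(rows) + 1L]] <- list(
          site_id = sites$site_id[i], season = season, start = start,
          planned_minutes = as.integer(planned),
          has_pm_sensor = TRUE, has_gravimetric = TRUE, has_sound = TRUE
        )
        start <- start + planned * 60
      }
    }

    rot_idx <- which(sites$site_class == "rotating")
    if (length(rot_idx)) {
      rot_min <- config$rotating_days * MINUTES_PER_DAY
      n_slots <- max(1L, (n_days - config$rotating_days) %/% 7L + 1L)
      slots <- rep_len(seq_len(n_slots), length(rot_idx))
      slots <- sample(slots)
      for (k in seq_along(rot_idx)) {
        i <- rot_idx[k]
        day_off <- sample.int(5L, 1L) - 1L
        start_day <- win$start + (slots[k] - 1L) * 7L + day_off
        # keep the 3-day window inside the season
        latest <- win$end - config$rotating_days + 1L
        if (start_day > latest) start_day <- latest
        start <- as_naive_posix(start_day) + 10 * 3600
        rows[[length(rows) + 1L]] <- list(
          site_id = sites$site_id[i], season = season, start = start,
          planned_minutes = rot_min,
          has_pm_sensor = TRUE, has_gravimetric = TRUE,
          has_sound = season == "wet"
        )
      }
    }
  }

  dep <- dplyr::bind_rows(lapply(rows, tibble::as_tibble))
  dep$deployment_id <- sprintf("D%04d", seq_len(nrow(dep)))

  fail <- runif(nrow(dep)) < config$failure_prob
  trunc_frac <- runif(nrow(dep), 0, 0.4)
  lost <- pmax(1L, as.integer(round(trunc_frac * dep$planned_minutes)))
  dep$achieved_minutes <- ifelse(fail, dep$planned_minutes - lost,
                                 dep$planned_minutes)
  dep$achieved_minutes <- as.integer(pmax(1L, dep$achieved_minutes))

  dplyr::select(dep, "deployment_id", "site_id", "season", "start",
                "planned_minutes", "achieved_minutes", "has_pm_sensor",
                "has_gravimetric", "has_sound")
}

#' Simulate true PM2.5 minute series
#'
#' Evaluates the latent exposure model over each deployment's achieved
#' window (or, when `deployments` is `NULL`, over each site's full season
#' windows, which is convenient for convergence checks on small
#' configurations).
#'
#' @param sites Site table.
#' @param config A [campaign_config()].
#' @param deployments Deployment table from
#'   [simulate_deployment_schedule()], or `NULL` for full-season series.
#' @return A tibble of minute observations: `deployment_id`, `site_id`,
#'   `season`, `timestamp`, `quantity = "pm_true"`, `value` (ug/m3).
#' @export
simulate_true_pm <- function(sites, config, deployments = NULL) {
  set.seed(stage_seed(config, "pm"))
  if (is.null(deployments)) {
    deployments <- full_season_deployments(sites, config)
  }
  dep <- deployments[deployments$has_pm_sensor | deployments$has_gravimetric, ]
  site_lookup <- sites[match(dep$site_id, sites$site_id), ]

  pieces <- vector("list", nrow(dep))
  for (k in seq_len(nrow(dep))) {
    n <- dep$achieved_minutes[k]
    ts <- minute_seq(dep$start[k], n)
    season <- dep$season[k]
    mu <- site_minute_mean(site_lookup[k, ], season, ts, config)
    noise <- exp(rnorm(n, -config$sigma_minute^2 / 2, config$sigma_minute))
    pieces[[k]] <- tibble::tibble(
      deployment_id = dep$deployment_id[k],
      site_id = dep$site_id[k],
      season = season,
      timestamp = ts,
      value = mu * noise
    )
  }
  out <- dplyr::bind_rows(pieces)
  out$quantity <- "pm_true"
  dplyr::select(out, "deployment_id", "site_id", "season", "timestamp",
                "quantity", "value")
}

# Deterministic mean structure at given minutes for one site.
site_minute_mean <- function(site, season, timestamps, config) {
  base <- season_base(config, season) *
    config$land_use_multipliers[[site$land_use]] *
    (if (site$high_range_flag) config$high_range_multiplier else 1) *
    site$site_factor
  wk <- week_index(timestamps, config$seasons[[season]]$start)
  tf <- trend_factor(config, season, wk)
  df <- diurnal_factors(config, season)
  dn <- ifelse(is_day_minute(timestamps), df[["day"]], df[["night"]])
  base * tf * dn
}

full_season_deployments <- function(sites, config) {
  rows <- list()
  for (season in SEASONS) {
    win <- config$seasons[[season]]
    n_min <- (as.integer(win$end - win$start) + 1L) * MINUTES_PER_DAY
    for (i in seq_len(nrow(sites))) {
      rows[[length(rows) + 1L]] <- tibble::tibble(
        deployment_id = sprintf("F_%s_%s", sites$site_id[i], season),
        site_id = sites$site_id[i], season = season,
        start = as_naive_posix(win$start),
        planned_minutes = n_min, achieved_minutes = n_min,
        has_pm_sensor = TRUE, has_gravimetric = TRUE, has_sound = TRUE
      )
    }
  }
  dplyr::bind_rows(rows)
}

#' Simulate the raw light-scattering sensor stream
#'
#' Applies the season-specific multiplicative sensor bias and additive
#' zero-mean Gaussian noise to the true series, truncating at zero:
#' `raw = bias * true + noise`.
#'
#' @param true_series Output of [simulate_true_pm()].
#' @param config A [campaign_config()].
#' @return Minute tibble with `quantity = "pm_sensor_raw"`.
#' @export
simulate_sensor_stream <- function(true_series, config) {
  if (!all(true_series$quantity == "pm_true"))
    abort("simulate_sensor_stream() expects a pm_true series",
          class = "airsound_error_input")
  if (!all(true_series$season %in% SEASONS))
    abort("unknown season in true series", class = "airsound_error_input")
  set.seed(stage_seed(config, "sensor"))
  bias <- config$sensor_bias[true_series$season]
  raw <- bias * true_series$value +
    rnorm(nrow(true_series), 0, config$sensor_noise_sd)
  out <- true_series
  out$quantity <- "pm_sensor_raw"
  out$value <- pmax(0, raw)
  out
}

#' Simulate one gravimetric filter sample
#'
#' The collected mass is the time-integral of the true concentration over
#' the achieved window times the duty-cycled flow, plus the season's
#' field-blank offset and weighing noise. Pre- and post-sampling weights
#' are generated in triplicate within the weighing acceptance spread;
#' attenuation is generated from the configured BC mass fraction through
#' the same optics convention the lab stage inverts. Blanks carry the
#' offsets only.
#'
#' @param true_series Minute tibble (quantity `pm_true`) for one
#'   deployment, or `NULL` for a blank.
#' @param deployment One-row deployment tibble.
#' @param config A [campaign_config()].
#' @param is_blank Generate a field blank instead of a sample.
#' @param filter_id Identifier for the filter.
#' @return One-row tibble with triplicate masses, attenuations, flow,
#'   duty cycle, blank flag and season.
#' @export
simulate_filter_sample <- function(true_series, deployment, config,
                                   is_blank = FALSE,
                                   filter_id = paste0("F_", deployment$deployment_id)) {
  season <- deployment$season
  if (!is_blank) {
    if (is.null(true_series) || nrow(true_series) == 0)
      abort("gravimetric sample requires achieved minutes",
            class = "airsound_error_input")
    vol <- sampled_volume(nrow(true_series), config$flow_rate,
                          config$duty_cycle)
    mass_delta <- mean(true_series$value) * vol + config$mass_blank[[season]]
    bc_loading <- mean(true_series$value) * config$bc_fraction[[season]] *
      vol / lab_constants()$filter_area
    atn_delta <- bc_loading * lab_constants()$mac + config$atn_blank[[season]]
  } else {
    mass_delta <- config$mass_blank[[season]]
    atn_delta <- config$atn_blank[[season]]
  }

  trip <- function(center) {
    center + rnorm(3, 0, config$weighing_sd)
  }
  pre <- trip(config$tare_mass)
  post <- trip(config$tare_mass + mass_delta)
  pre_atn <- 4 + abs(rnorm(1, 0, 0.5))
  tibble::tibble(
    filter_id = filter_id,
    deployment_id = deployment$deployment_id,
    season = season,
    pre_mass_1 = pre[1], pre_mass_2 = pre[2], pre_mass_3 = pre[3],
    post_mass_1 = post[1], post_mass_2 = post[2], post_mass_3 = post[3],
    pre_atn = pre_atn,
    post_atn = pre_atn + atn_delta + rnorm(1, 0, config$atn_noise_sd),
    flow_rate = config$flow_rate,
    duty_cycle = config$duty_cycle,
    is_blank = is_blank
  )
}

#' Simulate all filter samples for a campaign
#'
#' One filter per gravimetric deployment plus field blanks attached to a
#' configured fraction of deployments.
#'
#' @inheritParams simulate_true_pm
#' @param true_series Output of [simulate_true_pm()].
#' @return Filter tibble (one row per filter, blanks included).
#' @export
simulate_filter_samples <- function(true_series, deployments, config) {
  set.seed(stage_seed(config, "filters"))
  grav <- deployments[deployments$has_gravimetric, ]
  split_true <- split(true_series, true_series$deployment_id)
  out <- vector("list", nrow(grav))
  for (k in seq_len(nrow(grav))) {
    out[[k]] <- simulate_filter_sample(split_true[[grav$deployment_id[k]]],
                                       grav[k, ], config)
  }
  samples <- dplyr::bind_rows(out)

  n_blank <- round(config$blank_frac * nrow(grav))
  if (n_blank > 0) {
    idx <- sample(nrow(grav), n_blank)
    blanks <- vector("list", n_blank)
    for (j in seq_len(n_blank)) {
      k <- idx[j]
      blanks[[j]] <- simulate_filter_sample(
        NULL, grav[k, ], config, is_blank = TRUE,
        filter_id = paste0("B_", grav$deployment_id[k])
      )
    }
    samples <- dplyr::bind_rows(samples, dplyr::bind_rows(blanks))
  }
  samples
}

#' Simulate A-weighted sound minute series
#'
#' Minute dBA = land-use background + site offset + day/night offset +
#' scheduled event boosts (e.g. calls to prayer) + Gaussian noise,
#' clamped to the configured dBA bounds.
#'
#' @param sites Site table.
#' @param config A [campaign_config()].
#' @param deployments Deployment table; only rows with `has_sound` are
#'   simulated.
#' @return Minute tibble with `quantity = "sound_dba"`.
#' @export
simulate_sound_stream <- function(sites, config, deployments) {
  set.seed(stage_seed(config, "sound"))
  miss <- setdiff(unique(sites$land_use), names(config$sound_background))
  if (length(miss))
    abort(paste("no sound background configured for land use:",
                paste(miss, collapse = ", ")),
          class = "airsound_error_config")

  site_off <- rnorm(nrow(sites), 0, config$sound_site_sd)
  names(site_off) <- sites$site_id

  ev_min <- event_minutes_of_day(config)
  dep <- deployments[deployments$has_sound, ]
  site_lookup <- sites[match(dep$site_id, sites$site_id), ]
  pieces <- vector("list", nrow(dep))
  for (k in seq_len(nrow(dep))) {
    n <- dep$achieved_minutes[k]
    ts <- minute_seq(dep$start[k], n)
    mod <- minute_of_day(ts)
    level <- config$sound_background[[site_lookup$land_use[k]]] +
      site_off[[dep$site_id[k]]] +
      ifelse(is_day_minute(ts), config$sound_day_offset,
             config$sound_night_offset) +
      ifelse(mod %in% ev_min, config$event_boost, 0) +
      rnorm(n, 0, config$sound_noise_sd)
    pieces[[k]] <- tibble::tibble(
      deployment_id = dep$deployment_id[k],
      site_id = dep$site_id[k],
      season = dep$season[k],
      timestamp = ts,
      value = pmin(pmax(level, config$sound_bounds[1]),
                   config$sound_bounds[2])
    )
  }
  out <- dplyr::bind_rows(pieces)
  out$quantity <- "sound_dba"
  dplyr::select(out, "deployment_id", "site_id", "season", "timestamp",
                "quantity", "value")
}

event_minutes_of_day <- function(config) {
  if (!length(config$event_times)) return(integer())
  parts <- strsplit(config$event_times, ":", fixed = TRUE)
  starts <- vapply(parts, function(p)
    as.integer(p[1]) * 60L + as.integer(p[2]), integer(1))
  unique(unlist(lapply(starts, function(s)
    (s + seq_len(config$event_minutes) - 1L) %% MINUTES_PER_DAY)))
}

#' Simulate a complete campaign
#'
#' Convenience wrapper running the whole generator: site network,
#' deployment schedule, true PM, raw sensor stream, filter samples and
#' sound stream.
#'
#' @param config A [campaign_config()].
#' @return A list with elements `config`, `sites`, `deployments`,
#'   `pm_true`, `pm_raw`, `filters`, `sound`.
#' @export
simulate_campaign <- function(config = campaign_config()) {
  sites <- generate_site_network(config)
  deployments <- simulate_deployment_schedule(sites, config)
  pm_true <- simulate_true_pm(sites, config, deployments)
  pm_raw <- simulate_sensor_stream(pm_true, config)
  filters <- simulate_filter_samples(pm_true, deployments, config)
  sound <- simulate_sound_stream(sites, config, deployments)
  list(config = config, sites = sites, deployments = deployments,
       pm_true = pm_true, pm_raw = pm_raw, filters = filters,
       sound = sound)
}
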