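# Season-specific calibration of light-scattering PM2.5 sensors against
# co-located gravimetric filters. The regression direction is
# gravimetric ~ sensor, so a fitted model is applied per minute as
# corrected = intercept + slope * raw.

#' Build sensor/gravimetric calibration pairs
#'
#' One pair per deployment that carries both a PM sensor and a usable
#' gravimetric result: the deployment-mean raw sensor value over the
#' filter's sampling window against the filter concentration.
#'
#' @param minutes Raw sensor minute tibble (quantity `pm_sensor_raw`).
#' @param gravimetric Results from [process_filters()].
#' @param deployments Deployment table.
#' @param sites Site table (supplies the high-range flag).
#' @param min_minutes Minimum sensor minutes required to form a pair.
#' @return Tibble of pairs: `deployment_id`, `site_id`, `season`,
#'   `site_group` (`general`/`high_range`), `sensor_mean`, `grav_conc`,
#'   `n_minutes`.
#' @export
build_pairs <- function(minutes, gravimetric, deployments, sites,
                        min_minutes = 60L) {
  grav <- gravimetric[!is.na(gravimetric$pm_conc), ]
  sens <- dplyr::summarise(
    dplyr::group_by(minutes, .data$deployment_id),
    sensor_mean = mean(.data$value), n_minutes = dplyr::n(),
    .groups = "drop"
  )
  pairs <- dplyr::inner_join(sens, grav[, c("deployment_id", "pm_conc")],
                             by = "deployment_id")
  pairs <- pairs[pairs$n_minutes >= min_minutes, ]
  if (!nrow(pairs)) {
    warn("no deployments with overlapping sensor and gravimetric data")
    return(tibble::tibble(deployment_id = character(), site_id = character(),
                          season = character(), site_group = character(),
                          sensor_mean = numeric(), grav_conc = numeric(),
                          n_minutes = integer()))
  }
  dep <- deployments[match(pairs$deployment_id, deployments$deployment_id), ]
  hr <- sites$high_range_flag[match(dep$site_id, sites$site_id)]
  tibble::tibble(
    deployment_id = pairs$deployment_id,
    site_id = dep$site_id,
    season = dep$season,
    site_group = ifelse(hr, "high_range", "general"),
    sensor_mean = pairs$sensor_mean,
    grav_conc = pairs$pm_conc,
    n_minutes = pairs$n_minutes
  )
}

#' Fit a season-specific sensor correction
#'
#' Ordinary least squares of the gravimetric concentration on the
#' deployment-mean sensor value for one season and site group, giving
#' the linear correction `corrected = intercept + slope * raw`.
#'
#' @param pairs Pair table from [build_pairs()].
#' @param season `"dry"` or `"wet"`.
#' @param site_group `"general"` or `"high_range"`.
#' @return A `calibration_model` list: `season`, `site_group`,
#'   `intercept`, `slope`, `n_pairs`, `r_squared`, `rmse`.
#' @export
fit_season_correction <- function(pairs, season, site_group = "general") {
  p <- pairs[pairs$season == season & pairs$site_group == site_group, ]
  if (nrow(p) < 3)
    abort(sprintf("only %d calibration pairs for %s/%s (need >= 3)",
                  nrow(p), season, site_group),
          class = "airsound_error_insufficient_data")
  if (var(p$sensor_mean) == 0)
    abort("sensor means have zero variance: degenerate fit",
          class = "airsound_error_degenerate_fit")
  fit <- lm(grav_conc ~ sensor_mean, data = p)
  slope <- unname(coef(fit)[2])
  if (slope <= 0)
    warn("fitted calibration slope is not positive")
  resid <- p$grav_conc - fitted(fit)
  structure(list(
    season = season,
    site_group = site_group,
    intercept = unname(coef(fit)[1]),
    slope = slope,
    n_pairs = nrow(p),
    r_squared = summary(fit)$r.squared,
    rmse = sqrt(mean(resid^2))
  ), class = "calibration_model")
}

#' @export
print.calibration_model <- function(x, ...) {
  cat(sprintf(
    "Sensor calibration [%s/%s]: corrected = %.3f + %.4f * raw (n = %d, R^2 = %.3f, RMSE = %.2f)\n",
    x$season, x$site_group, x$intercept, x$slope, x$n_pairs,
    x$r_squared, x$rmse))
  invisible(x)
}

#' Linearity diagnostic for the sensor/gravimetric relationship
#'
#' Compares the linear calibration against a more flexible fit (a
#' single-knot piecewise-linear spline with the interior knot at the
#' median sensor mean). A material drop in RMSE under the flexible fit
#' flags curvature that a straight-line correction would miss.
#'
#' @param pairs Pair table (one season/stratum; >= 10 pairs).
#' @param improvement_threshold Fractional RMSE improvement above which
#'   non-linearity is flagged (default 0.10).
#' @return List: `rmse_linear`, `rmse_flexible`, `improvement`
#'   (fractional), `nonlinear` flag, `knot`.
#' @export
check_linearity <- function(pairs, improvement_threshold = 0.10) {
  if (nrow(pairs) < 10)
    abort("need >= 10 pairs for the linearity check",
          class = "airsound_error_insufficient_data")
  x <- pairs$sensor_mean
  y <- pairs$grav_conc
  knot <- median(x)
  lin <- lm(y ~ x)
  flex <- lm(y ~ x + pmax(x - knot, 0))
  rmse <- function(fit) sqrt(mean(residuals(fit)^2))
  r_lin <- rmse(lin)
  r_flex <- rmse(flex)
  # a numerically exact linear fit leaves only rounding noise: no signal
  tol <- 1e-8 * (1 + mean(abs(y)))
  improvement <- if (r_lin > tol) (r_lin - r_flex) / r_lin else 0
  list(rmse_linear = r_lin, rmse_flexible = r_flex,
       improvement = improvement,
       nonlinear = improvement > improvement_threshold,
       knot = knot, n_pairs = nrow(pairs))
}

#' Apply a calibration model to a raw sensor stream
#'
#' Maps every minute through `intercept + slope * value`, flooring at
#' zero (floored minutes are counted in attribute `n_floored`).
#'
#' @param raw_series Minute tibble (quantity `pm_sensor_raw`).
#' @param model A `calibration_model`.
#' @return Minute tibble with `quantity = "pm_corrected"`.
#' @export
apply_correction <- function(raw_series, model) {
  seasons <- unique(raw_series$season)
  if (!all(seasons == model$season))
    abort(sprintf("model season '%s' does not match series season(s) %s",
                  model$season, paste(seasons, collapse = ", ")),
          class = "airsound_error_input")
  corrected <- floor_at_zero(model$intercept + model$slope * raw_series$value)
  out <- raw_series
  out$quantity <- "pm_corrected"
  out$value <- as.numeric(corrected)
  attr(out, "n_floored") <- sum(attr(corrected, "floored"))
  out
}

#' Mean sensor under/overestimation
#'
#' `100 * (1 - mean(sensor) / mean(gravimetric))`: positive values mean
#' the sensor underestimates the gravimetric reference.
#'
#' @param pairs Pair table.
#' @param season Optional season filter.
#' @return Percent underestimate (negative = overestimate).
#' @export
sensor_bias_summary <- function(pairs, season = NULL) {
  if (!is.null(season)) pairs <- pairs[pairs$season == season, ]
  if (!nrow(pairs))
    abort("no pairs available", class = "airsound_error_insufficient_data")
  mg <- mean(pairs$grav_conc)
  if (mg == 0)
    abort("gravimetric mean is zero", class = "airsound_error_input")
  100 * (1 - mean(pairs$sensor_mean) / mg)
}

#' Fit the full set of campaign calibration models
#'
#' One general model per season, plus a separate high-range model per
#' season when at least three high-range pairs exist (otherwise the
#' high-range stratum falls back to the general model with a warning).
#'
#' @param pairs Pair table from [build_pairs()].
#' @return Named list of `calibration_model` objects keyed
#'   `"<season>.<site_group>"`.
#' @export
fit_campaign_models <- function(pairs) {
  models <- list()
  for (season in intersect(SEASONS, unique(pairs$season))) {
    models[[paste(season, "general", sep = ".")]] <-
      fit_season_correction(pairs, season, "general")
    n_hr <- sum(pairs$season == season & pairs$site_group == "high_range")
    if (n_hr >= 3) {
      hr <- tryCatch(fit_season_correction(pairs, season, "high_range"),
                     airsound_error_degenerate_fit = function(e) NULL)
      if (is.null(hr)) {
        warn(sprintf(
          "high-range stratum degenerate in %s season: falling back to the general model",
          season))
      } else {
        models[[paste(season, "high_range", sep = ".")]] <- hr
      }
    } else if (n_hr > 0) {
      warn(sprintf(
        "only %d high-range pairs in %s season: falling back to the general model",
        n_hr, season))
    }
  }
  models
}

#' Apply the campaign model set to the raw stream
#'
#' Routes every deployment's minutes through the model matching its
#' season and site group (high-range falls back to general).
#'
#' @param minutes Raw sensor minute tibble.
#' @param models Output of [fit_campaign_models()].
#' @param sites Site table (for the high-range flag).
#' @return Corrected minute tibble (quantity `pm_corrected`).
#' @export
apply_campaign_models <- function(minutes, models, sites) {
  hr_sites <- sites$site_id[sites$high_range_flag]
  group <- ifelse(minutes$site_id %in% hr_sites, "high_range", "general")
  key <- paste(minutes$season, group, sep = ".")
  fallback <- paste(minutes$season, "general", sep = ".")
  key[!key %in% names(models)] <- fallback[!key %in% names(models)]
  out <- minutes
  pieces <- lapply(split(seq_len(nrow(minutes)), key), function(idx) {
    m <- models[[key[idx[1]]]]
    sub <- minutes[idx, ]
    apply_correction(sub, m)
  })
  out <- dplyr::bind_rows(pieces)
  dplyr::arrange(out, .data$deployment_id, .data$timestamp)
}
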