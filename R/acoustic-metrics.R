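# Energy-based sound metrics from minute-level A-weighted levels.
#
# Decibels are logarithmic, so time averaging happens on the energy
# scale 10^(L/10): the equivalent continuous level LAeq is the constant
# level carrying the same total acoustic energy as the series. The
# intermittency ratio (IR) is the share of total energy contributed by
# "event" minutes that stand out from the window's own LAeq by at least
# a threshold K.

#' Equivalent continuous sound level (LAeq)
#'
#' `LAeq = 10 * log10(mean(10^(L/10)))` over the minute levels.
#'
#' @param values Numeric minute levels (dBA).
#' @return LAeq (dBA).
#' @export
laeq <- function(values) {
  values <- values[!is.na(values)]
  if (!length(values) || any(!is.finite(values)))
    abort("laeq() needs at least one finite level",
          class = "airsound_error_input")
  10 * log10(mean(10^(values / 10)))
}

#' Day- or night-window LAeq
#'
#' LAeq restricted to minutes whose clock time falls in the day window
#' (06:00--20:59) or the night window (21:00--05:59).
#'
#' @param series Tibble with `timestamp` and `value`.
#' @param window `"day"` or `"night"`.
#' @return LAeq (dBA) of the window.
#' @export
window_laeq <- function(series, window = c("day", "night")) {
  window <- match.arg(window)
  day <- is_day_minute(series$timestamp)
  v <- series$value[if (window == "day") day else !day]
  if (!length(v))
    abort(sprintf("no minutes in the %s window", window),
          class = "airsound_error_input")
  laeq(v)
}

#' Intermittency ratio
#'
#' Event minutes are those whose level is at least `threshold_k` dBA
#' above the window's own LAeq; the IR is the percentage of total
#' acoustic energy contributed by event minutes:
#' `IR = 100 * sum(10^(L_event/10)) / sum(10^(L/10))`.
#'
#' @param values Numeric minute levels (dBA) of one window.
#' @param threshold_k Event threshold above the window LAeq (dBA,
#'   default 4).
#' @return IR in percent (0--100).
#' @export
intermittency_ratio <- function(values, threshold_k = 4) {
  if (threshold_k <= 0)
    abort("threshold_k must be positive", class = "airsound_error_input")
  la <- laeq(values)
  values <- values[!is.na(values)]
  energy <- 10^(values / 10)
  events <- values >= la + threshold_k
  100 * sum(energy[events]) / sum(energy)
}

#' IR sensitivity across event thresholds
#'
#' @param values Numeric minute levels (dBA).
#' @param thresholds Event thresholds to evaluate (dBA).
#' @return Tibble `threshold`, `ir`; IR is non-increasing in the
#'   threshold.
#' @export
ir_sensitivity <- function(values, thresholds = c(3, 4, 5)) {
  tibble::tibble(
    threshold = thresholds,
    ir = vapply(thresholds, function(k)
      intermittency_ratio(values, k), numeric(1))
  )
}

#' Per-site sound metric set
#'
#' Pools each site's minutes (across deployments and seasons) and
#' computes LAeq, Lday, Lnight and the overall, daytime and nighttime
#' intermittency ratios, each IR using its own window's LAeq as the
#' event reference.
#'
#' @param minutes Sound minute tibble (`site_id`, `timestamp`, `value`).
#' @param threshold_k IR event threshold (dBA).
#' @return Tibble: `site_id`, `laeq`, `l_day`, `l_night`, `ir`,
#'   `ir_day`, `ir_night`, `n_minutes`, `n_day_minutes`,
#'   `n_night_minutes`, `threshold_k`.
#' @export
sound_site_metrics <- function(minutes, threshold_k = 4) {
  day <- is_day_minute(minutes$timestamp)
  per_site <- function(v, d) {
    tibble::tibble(
      laeq = laeq(v),
      l_day = if (any(d)) laeq(v[d]) else NA_real_,
      l_night = if (any(!d)) laeq(v[!d]) else NA_real_,
      ir = intermittency_ratio(v, threshold_k),
      ir_day = if (any(d)) intermittency_ratio(v[d], threshold_k) else NA_real_,
      ir_night = if (any(!d)) intermittency_ratio(v[!d], threshold_k) else NA_real_,
      n_minutes = length(v),
      n_day_minutes = sum(d),
      n_night_minutes = sum(!d),
      threshold_k = threshold_k
    )
  }
  idx <- split(seq_len(nrow(minutes)), minutes$site_id)
  out <- dplyr::bind_rows(lapply(idx, function(i)
    per_site(minutes$value[i], day[i])), .id = "site_id")
  out
}

#' Diurnal profile
#'
#' Hourly statistic of minute values across the 24-h clock (median for
#' sound, mean for PM), or a centred 15-minute rolling average at
#' minute-of-day resolution when `rolling_minutes > 0` (the window wraps
#' around midnight).
#'
#' @param series Tibble with `timestamp` and `value`.
#' @param stat `"median"` or `"mean"`.
#' @param rolling_minutes 0 for hourly output, or an odd window length
#'   (e.g. 15) for a minute-resolution rolling mean profile.
#' @return Tibble `hour`/`minute_of_day` and `value`; hours with no data
#'   are reported as `NA`.
#' @export
diurnal_profile <- function(series, stat = c("median", "mean"),
                            rolling_minutes = 0) {
  stat <- match.arg(stat)
  f <- if (stat == "median") median else mean
  if (rolling_minutes > 0) {
    mod <- minute_of_day(series$timestamp)
    prof <- vapply(0:1439, function(m) {
      v <- series$value[mod == m]
      if (length(v)) f(v) else NA_real_
    }, numeric(1))
    k <- rolling_minutes
    roll <- as.numeric(stats::filter(prof, rep(1 / k, k), sides = 2,
                                     circular = TRUE))
    return(tibble::tibble(minute_of_day = 0:1439, value = roll))
  }
  h <- hour_of(series$timestamp)
  prof <- vapply(0:23, function(hh) {
    v <- series$value[h == hh]
    if (length(v)) f(v) else NA_real_
  }, numeric(1))
  tibble::tibble(hour = 0:23, value = prof)
}

#' Guideline set
#'
#' Reference limits used in exceedance reports: WHO traffic-noise
#' guidance (53 dBA day, 45 dBA night), Bangladesh area-based limits
#' (residential 55 dBA day / 50 dBA night; industrial 75 dBA day /
#' 70 dBA night), and the WHO 24-h PM2.5 guideline (15 ug/m^3).
#'
#' @param who_sound_day,who_sound_night WHO traffic-noise limits (dBA).
#' @param bd_residential_day,bd_residential_night Bangladesh residential
#'   limits (dBA).
#' @param bd_industrial_day,bd_industrial_night Bangladesh industrial
#'   limits (dBA).
#' @param who_pm25_24h WHO 24-h PM2.5 guideline (ug/m^3).
#' @return Named list of limits.
#' @export
guideline_set <- function(who_sound_day = 53, who_sound_night = 45,
                          bd_residential_day = 55,
                          bd_residential_night = 50,
                          bd_industrial_day = 75,
                          bd_industrial_night = 70,
                          who_pm25_24h = 15) {
  lims <- list(who_sound_day = who_sound_day,
               who_sound_night = who_sound_night,
               bd_residential_day = bd_residential_day,
               bd_residential_night = bd_residential_night,
               bd_industrial_day = bd_industrial_day,
               bd_industrial_night = bd_industrial_night,
               who_pm25_24h = who_pm25_24h)
  stopifnot(all(unlist(lims) > 0))
  lims
}

#' Guideline exceedance report
#'
#' Computes (a) the percentage of day-window minutes below the WHO
#' daytime limit and night-window minutes below the WHO nighttime limit,
#' (b) per-site pass/fail flags against the Bangladesh land-use limits
#' (residential sites against residential limits, commercial/industrial
#' sites against industrial limits; other land uses are not covered by a
#' limit and reported as `NA`), comparing the site's Lday/Lnight, and
#' (c) when daily PM data are supplied, the percentage of measurement-
#' days above the WHO 24-h PM2.5 guideline.
#'
#' @param sound_minutes Sound minute tibble.
#' @param site_metrics Output of [sound_site_metrics()].
#' @param sites Site table (for land use).
#' @param pm_daily Optional daily PM tibble with a `value` column.
#' @param guidelines A [guideline_set()].
#' @return List: `minutes_below` (tibble window/limit/pct_below),
#'   `site_flags`, `pm_days_above_pct` (or `NA`).
#' @export
guideline_exceedance <- function(sound_minutes, site_metrics = NULL,
                                 sites = NULL, pm_daily = NULL,
                                 guidelines = guideline_set()) {
  day <- is_day_minute(sound_minutes$timestamp)
  pct_below <- function(v, lim) 100 * mean(v < lim)
  minutes_below <- tibble::tibble(
    window = c("day", "night"),
    limit = c(guidelines$who_sound_day, guidelines$who_sound_night),
    pct_below = c(
      pct_below(sound_minutes$value[day], guidelines$who_sound_day),
      pct_below(sound_minutes$value[!day], guidelines$who_sound_night)
    )
  )

  site_flags <- NULL
  if (!is.null(site_metrics) && !is.null(sites)) {
    lu <- sites$land_use[match(site_metrics$site_id, sites$site_id)]
    lim_day <- ifelse(lu == "residential", guidelines$bd_residential_day,
                ifelse(lu == "commercial_industrial",
                       guidelines$bd_industrial_day, NA_real_))
    lim_night <- ifelse(lu == "residential", guidelines$bd_residential_night,
                  ifelse(lu == "commercial_industrial",
                         guidelines$bd_industrial_night, NA_real_))
    site_flags <- tibble::tibble(
      site_id = site_metrics$site_id,
      land_use = lu,
      exceeds_day = site_metrics$l_day > lim_day,
      exceeds_night = site_metrics$l_night > lim_night
    )
  }

  pm_pct <- NA_real_
  if (!is.null(pm_daily) && nrow(pm_daily))
    pm_pct <- 100 * mean(pm_daily$value > guidelines$who_pm25_24h)

  list(minutes_below = minutes_below, site_flags = site_flags,
       pm_days_above_pct = pm_pct)
}

#' Median/IQR sound summary by group
#'
#' Cross-site summaries of the per-site sound metric set use medians and
#' interquartile ranges because the decibel scale is non-linear.
#'
#' @param site_metrics Output of [sound_site_metrics()].
#' @param sites Site table.
#' @param group Grouping column in `sites`.
#' @return Tibble of group medians and IQRs for each metric.
#' @export
sound_group_summary <- function(site_metrics, sites, group = "land_use") {
  df <- dplyr::inner_join(site_metrics, sites[, c("site_id", group)],
                          by = "site_id")
  cols <- c("laeq", "l_day", "l_night", "ir", "ir_day", "ir_night")
  grouped <- dplyr::group_by(df, dplyr::across(dplyr::all_of(group)))
  dplyr::summarise(
    grouped,
    n_sites = dplyr::n(),
    dplyr::across(dplyr::all_of(cols),
                  list(median = ~median(.x, na.rm = TRUE),
                       iqr = ~stats::IQR(.x, na.rm = TRUE))),
    .groups = "drop"
  )
}
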