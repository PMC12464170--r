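# Weekly temporal adjustment of rotating-site measurements.
#
# Short rotating deployments sample different weeks of a season, so raw
# site means confound space with time. The weekly temporal adjustment
# factor (TAF) is the ratio of the reference network's weekly mean
# (continuously monitored fixed sites, optionally averaged with an
# external regulatory monitor for PM2.5) to its seasonal mean; dividing
# a deployment's values by the TAF of its week removes the shared
# within-season trend.

#' Daily means from retained measurement-days
#'
#' Collapses retained minute data (output of [completeness_filter()]) to
#' one row per deployment and measurement-day, with all-day, day-window
#' and night-window means and the calendar date of the block start.
#'
#' @param minutes Retained minute tibble carrying a `measurement_day`
#'   column.
#' @return Tibble: `deployment_id`, `site_id`, `season`,
#'   `measurement_day`, `day_date`, `value`, `day_value`, `night_value`,
#'   `n_minutes`.
#' @export
daily_means <- function(minutes) {
  minutes$.is_day <- is_day_minute(minutes$timestamp)
  out <- dplyr::summarise(
    dplyr::group_by(minutes, .data$deployment_id, .data$site_id,
                    .data$season, .data$measurement_day),
    day_date = as.Date(min(.data$timestamp), tz = "UTC"),
    day_value = mean(.data$value[.data$.is_day]),
    night_value = mean(.data$value[!.data$.is_day]),
    value = mean(.data$value),
    n_minutes = dplyr::n(),
    .groups = "drop"
  )
  out
}

#' Weekly reference mean
#'
#' The reference level for one season-week: the mean over included fixed
#' sites of their site-level weekly mean of daily values, optionally
#' averaged (equal weight) with an external reference monitor's weekly
#' mean. Sites in `exclude_sites` (e.g. an extreme high-range site) are
#' removed before pooling.
#'
#' @param fixed_daily Daily tibble ([daily_means()]) for fixed sites in
#'   one season.
#' @param week Week index (see [week_index()]).
#' @param season_start First day of the season window.
#' @param exclude_sites Character vector of site ids to exclude.
#' @param external_daily Optional external reference tibble with
#'   `day_date` and `value`.
#' @return Reference mean (ug/m^3) for the week.
#' @export
weekly_reference_mean <- function(fixed_daily, week, season_start,
                                  exclude_sites = character(),
                                  external_daily = NULL) {
  d <- fixed_daily[!fixed_daily$site_id %in% exclude_sites, ]
  d <- d[week_index(d$day_date, season_start) == week, ]
  ext <- NULL
  if (!is.null(external_daily)) {
    e <- external_daily[week_index(external_daily$day_date, season_start) == week, ]
    if (nrow(e)) ext <- mean(e$value)
  }
  if (!nrow(d) && is.null(ext))
    abort(sprintf("no reference data in week %d", week),
          class = "airsound_error_missing_week")
  pooled <- if (nrow(d)) {
    site_means <- tapply(d$value, d$site_id, mean)
    mean(site_means)
  } else NULL
  mean(c(pooled, ext))
}

weekly_reference_table <- function(fixed_daily, season_start,
                                   exclude_sites = character(),
                                   external_daily = NULL) {
  d <- fixed_daily[!fixed_daily$site_id %in% exclude_sites, ]
  weeks <- sort(unique(c(
    week_index(d$day_date, season_start),
    if (!is.null(external_daily))
      week_index(external_daily$day_date, season_start)
  )))
  ref <- vapply(weeks, function(w)
    weekly_reference_mean(fixed_daily, w, season_start, exclude_sites,
                          external_daily), numeric(1))
  n_days <- vapply(weeks, function(w) {
    dd <- unique(c(
      d$day_date[week_index(d$day_date, season_start) == w],
      if (!is.null(external_daily))
        external_daily$day_date[
          week_index(external_daily$day_date, season_start) == w]
    ))
    length(dd)
  }, integer(1))
  tibble::tibble(week = weeks, ref_mean = ref, n_days = n_days)
}

#' Compute the weekly TAF table
#'
#' `TAF(week) = weekly reference mean / seasonal reference mean`, where
#' the seasonal reference mean defaults to the duration-weighted mean of
#' the weekly reference means (weights = number of reference days per
#' week), so the duration-weighted mean TAF is exactly 1.
#'
#' @param weekly_means Tibble with `week`, `ref_mean` and (for
#'   weighting) `n_days`, e.g. from the fixed-site reference network.
#' @param seasonal_reference_mean Optional externally supplied seasonal
#'   mean (must be positive).
#' @param season,pollutant Labels stored on the table.
#' @return A `taf_table` tibble: `week`, `ref_mean`, `n_days`, `taf`;
#'   attributes `seasonal_reference_mean`, `season`, `pollutant`.
#' @export
compute_taf <- function(weekly_means, seasonal_reference_mean = NULL,
                        season = NA_character_, pollutant = "pm25") {
  if (!"n_days" %in% names(weekly_means)) weekly_means$n_days <- 1L
  if (is.null(seasonal_reference_mean)) {
    seasonal_reference_mean <-
      sum(weekly_means$ref_mean * weekly_means$n_days) /
      sum(weekly_means$n_days)
  }
  if (!is.finite(seasonal_reference_mean) || seasonal_reference_mean <= 0)
    abort("seasonal reference mean must be positive",
          class = "airsound_error_input")
  out <- weekly_means
  out$taf <- out$ref_mean / seasonal_reference_mean
  structure(out, class = c("taf_table", class(out)),
            seasonal_reference_mean = seasonal_reference_mean,
            season = season, pollutant = pollutant)
}

#' TAF lookup with neighbour interpolation
#'
#' Returns the TAF for each requested week; weeks missing from the table
#' are linearly interpolated between their nearest observed neighbours.
#' Weeks outside the observed range raise a missing-week error.
#'
#' @param taf_table A [compute_taf()] table.
#' @param weeks Integer week indices.
#' @return Numeric TAF values.
#' @export
taf_for_week <- function(taf_table, weeks) {
  if (nrow(taf_table) == 1) {
    out <- ifelse(weeks == taf_table$week, taf_table$taf, NA_real_)
  } else {
    out <- stats::approx(taf_table$week, taf_table$taf, xout = weeks,
                         rule = 1)$y
  }
  if (anyNA(out))
    abort(sprintf("no TAF (and no interpolable neighbours) for week(s) %s",
                  paste(unique(weeks[is.na(out)]), collapse = ", ")),
          class = "airsound_error_missing_week")
  out
}

#' Deployment week assignment
#'
#' Each deployment is assigned to the season-week containing its
#' midpoint (start + achieved duration / 2).
#'
#' @param deployments Deployment table.
#' @param season_starts Named Date vector (`dry`, `wet`) of season window
#'   starts.
#' @return Tibble `deployment_id`, `season`, `week`.
#' @export
deployment_week <- function(deployments, season_starts) {
  mid <- deployments$start + 60 * deployments$achieved_minutes / 2
  tibble::tibble(
    deployment_id = deployments$deployment_id,
    season = deployments$season,
    week = week_index(mid, as.Date(season_starts[deployments$season]))
  )
}

#' Apply the TAF to measurement values
#'
#' Divides each deployment's values by the TAF of its assigned week.
#' Applied at the measurement-day (or deployment) level: the TAF is a
#' weekly scalar, so within-day structure is preserved.
#'
#' @param values Tibble with a `deployment_id` column and the value
#'   columns to adjust.
#' @param taf_table A [compute_taf()] table for the matching season.
#' @param deployment_weeks Output of [deployment_week()] (same season).
#' @param cols Character vector of value columns to divide by the TAF.
#' @return `values` with the listed columns adjusted and a `taf` column
#'   appended.
#' @export
apply_taf <- function(values, taf_table, deployment_weeks,
                      cols = "value") {
  wk <- deployment_weeks$week[
    match(values$deployment_id, deployment_weeks$deployment_id)]
  if (anyNA(wk))
    abort("values reference a deployment with no week assignment",
          class = "airsound_error_input")
  taf <- taf_for_week(taf_table, wk)
  out <- values
  for (cl in cols) out[[cl]] <- out[[cl]] / taf
  out$taf <- taf
  out
}

#' Seasonal site summary
#'
#' Season-specific mean and standard deviation of temporally-adjusted
#' daily PM2.5 per site (over retained measurement-days), day- and
#' night-window means, and adjusted BC with the BC/PM ratio when filter
#' results are supplied.
#'
#' @param adjusted_daily Adjusted daily PM tibble (from [apply_taf()] on
#'   [daily_means()] output).
#' @param bc_deployments Optional adjusted BC tibble with `site_id`,
#'   `season`, `bc_conc`.
#' @return Tibble: `site_id`, `season`, `n_days`, `pm_mean`, `pm_sd`,
#'   `pm_day_mean`, `pm_night_mean`, `bc_mean`, `bc_pm_ratio`.
#' @export
seasonal_site_mean <- function(adjusted_daily, bc_deployments = NULL) {
  if (!nrow(adjusted_daily))
    abort("no retained measurement-days", class = "airsound_error_input")
  out <- dplyr::summarise(
    dplyr::group_by(adjusted_daily, .data$site_id, .data$season),
    n_days = dplyr::n(),
    pm_mean = mean(.data$value),
    pm_sd = sd(.data$value),
    pm_day_mean = mean(.data$day_value, na.rm = TRUE),
    pm_night_mean = mean(.data$night_value, na.rm = TRUE),
    .groups = "drop"
  )
  if (!is.null(bc_deployments)) {
    bc <- dplyr::summarise(
      dplyr::group_by(bc_deployments, .data$site_id, .data$season),
      bc_mean = mean(.data$bc_conc, na.rm = TRUE), .groups = "drop")
    out <- dplyr::left_join(out, bc, by = c("site_id", "season"))
  } else {
    out$bc_mean <- NA_real_
  }
  out$bc_pm_ratio <- ifelse(
    is.finite(out$bc_mean) & out$pm_mean > 0,
    100 * out$bc_mean / out$pm_mean, NA_real_)
  out
}

#' Annual site summary
#'
#' The annual value at a site is the arithmetic mean of its available
#' seasonal means (each season weighted equally regardless of the number
#' of retained days).
#'
#' @param seasonal Seasonal summary from [seasonal_site_mean()], or any
#'   tibble with `site_id`, `season` and a `pm_mean` column (optionally
#'   `bc_mean`).
#' @return Tibble: `site_id`, `pm_annual`, `bc_annual`,
#'   `seasons_present`.
#' @export
annual_site_mean <- function(seasonal) {
  if (!nrow(seasonal))
    abort("no seasonal summaries", class = "airsound_error_input")
  if (!"bc_mean" %in% names(seasonal)) seasonal$bc_mean <- NA_real_
  dplyr::summarise(
    dplyr::group_by(seasonal, .data$site_id),
    pm_annual = mean(.data$pm_mean),
    bc_annual = if (all(is.na(.data$bc_mean))) NA_real_
                else mean(.data$bc_mean, na.rm = TRUE),
    seasons_present = paste(sort(unique(.data$season)), collapse = ","),
    .groups = "drop"
  )
}

#' Grouped summary of site-level values
#'
#' Group mean and standard deviation of site-level values per category
#' (site class or land use), optionally by season: the layout of a
#' campaign summary table.
#'
#' @param site_values Tibble with one row per site (or site-season) and
#'   the value columns to summarise.
#' @param sites Site table supplying the grouping column.
#' @param group Grouping column in `sites` (`"site_class"` or
#'   `"land_use"`).
#' @param cols Value columns to summarise.
#' @param sd_single How to report the SD of a single-site group:
#'   `"na"` (default) or `"zero"`.
#' @return Tibble with `n_sites`, and `<col>_mean` / `<col>_sd` per
#'   value column, by group (and `season` when present).
#' @export
group_summary <- function(site_values, sites, group = "land_use",
                          cols = "pm_annual", sd_single = c("na", "zero")) {
  sd_single <- match.arg(sd_single)
  df <- dplyr::inner_join(site_values,
                          sites[, c("site_id", group)], by = "site_id")
  if (!nrow(df)) {
    warn("no sites matched the grouping table")
    return(df)
  }
  keys <- c(group, intersect("season", names(df)))
  grouped <- dplyr::group_by(df, dplyr::across(dplyr::all_of(keys)))
  out <- dplyr::summarise(
    grouped,
    n_sites = dplyr::n_distinct(.data$site_id),
    dplyr::across(dplyr::all_of(cols),
                  list(mean = ~mean(.x, na.rm = TRUE),
                       sd = ~sd(.x, na.rm = TRUE))),
    .groups = "drop"
  )
  if (sd_single == "zero") {
    for (cl in paste0(cols, "_sd")) {
      out[[cl]][out$n_sites == 1] <- 0
    }
  }
  out
}
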