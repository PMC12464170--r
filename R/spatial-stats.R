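# Completeness filtering, land-use contrasts, correlation structure and
# bivariate hotspot classification.

#' Completeness filter and measurement-day slicing
#'
#' Flags deployments that missed their planned duration by more than
#' 10 h (600 minutes), slices each deployment's minutes into consecutive
#' 1440-minute measurement-days counted from the deployment start, and
#' retains only days with at least `completeness * 1440` observed
#' minutes.
#'
#' @param deployments Deployment table.
#' @param minutes Minute tibble for those deployments.
#' @param completeness Minimum observed fraction of a 1440-minute block
#'   (default 0.8).
#' @param target_gap_minutes Allowed shortfall for the "achieved within
#'   10 h of target" flag (default 600).
#' @return List: `report` (one row per deployment: `planned_minutes`,
#'   `achieved_minutes`, `achieved_within_10h`, `retained_days`) and
#'   `minutes` (retained minutes with a `measurement_day` column).
#' @export
completeness_filter <- function(deployments, minutes, completeness = 0.8,
                                target_gap_minutes = 600) {
  orphan <- setdiff(unique(minutes$deployment_id), deployments$deployment_id)
  if (length(orphan))
    abort(paste("minute series with no deployment record:",
                paste(orphan, collapse = ", ")),
          class = "airsound_error_input")

  dep <- deployments[match(minutes$deployment_id, deployments$deployment_id), ]
  offset_min <- as.numeric(difftime(minutes$timestamp, dep$start,
                                    units = "mins"))
  minutes$measurement_day <- as.integer(offset_min %/% MINUTES_PER_DAY) + 1L

  counts <- dplyr::count(minutes, .data$deployment_id, .data$measurement_day)
  keep <- counts[counts$n >= completeness * MINUTES_PER_DAY, ]
  retained <- dplyr::inner_join(
    minutes, keep[, c("deployment_id", "measurement_day")],
    by = c("deployment_id", "measurement_day"))

  achieved <- dplyr::count(minutes, .data$deployment_id,
                           name = "observed_minutes")
  rd <- dplyr::count(keep, .data$deployment_id, name = "retained_days")
  report <- deployments[, c("deployment_id", "site_id", "season",
                            "planned_minutes", "achieved_minutes")]
  report <- dplyr::left_join(report, achieved, by = "deployment_id")
  report <- dplyr::left_join(report, rd, by = "deployment_id")
  report$observed_minutes[is.na(report$observed_minutes)] <- 0L
  report$retained_days[is.na(report$retained_days)] <- 0L
  report$achieved_within_10h <-
    report$planned_minutes - report$achieved_minutes <= target_gap_minutes

  list(report = tibble::as_tibble(report),
       minutes = tibble::as_tibble(retained))
}

#' Day-of-week contrast with cluster-robust errors
#'
#' Weekday means of daily values plus a linear regression of the daily
#' value on weekday indicators with site-clustered (CR1) robust standard
#' errors, the appropriate inference when repeated days at a site are
#' correlated.
#'
#' @param daily Tibble with `value`, `site_id` and `day_date`.
#' @param ref Reference weekday for the contrasts (default `"Mon"`).
#' @return List: `weekday_means` tibble and `contrasts` tibble
#'   (`term`, `estimate`, `se_cluster`).
#' @export
day_of_week_contrast <- function(daily, ref = "Mon") {
  wd_labels <- c("Sun", "Mon", "Tue", "Wed", "Thu", "Fri", "Sat")
  wd <- wd_labels[as.POSIXlt(as_naive_posix(daily$day_date))$wday + 1L]
  if (length(unique(wd)) < 2)
    abort("need at least two weekdays represented",
          class = "airsound_error_input")
  if (length(unique(daily$site_id)) < 2)
    abort("cluster-robust errors need more than one site",
          class = "airsound_error_input")
  weekday_means <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(weekday = wd, value = daily$value),
                    .data$weekday),
    n = dplyr::n(), mean = mean(.data$value), .groups = "drop")

  f <- factor(wd, levels = c(ref, setdiff(wd_labels, ref)))
  f <- droplevels(f)
  fit <- lm(daily$value ~ f)
  vc <- sandwich::vcovCL(fit, cluster = daily$site_id, type = "HC1")
  contrasts <- tibble::tibble(
    term = sub("^f", "", names(coef(fit))),
    estimate = unname(coef(fit)),
    se_cluster = unname(sqrt(diag(vc)))
  )
  list(weekday_means = weekday_means, contrasts = contrasts)
}

#' Spearman correlation matrix of site-level metrics
#'
#' Pairwise Spearman rank correlations (average ranks for ties) between
#' site-averaged air and sound metrics. Pairs involving a constant
#' column are undefined and reported as `NA`.
#'
#' @param site_metrics Tibble with `site_id` plus numeric metric
#'   columns.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearman_matrix <- function(site_metrics) {
  num <- site_metrics[, vapply(site_metrics, is.numeric, logical(1)),
                      drop = FALSE]
  if (nrow(num) < 3)
    abort("need >= 3 sites with metrics", class = "airsound_error_input")
  m <- suppressWarnings(
    stats::cor(as.matrix(num), method = "spearman",
               use = "pairwise.complete.obs"))
  diag(m) <- 1
  m
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected Kruskal-Wallis H with the chi-squared approximation on
#' (groups - 1) degrees of freedom; used for land-use contrasts of
#' site-level exposure metrics.
#'
#' @param values Numeric vector.
#' @param groups Group labels (same length).
#' @return Tibble: `statistic`, `df`, `p_value`, `method`,
#'   `group_sizes`.
#' @export
kruskal_wallis <- function(values, groups) {
  ok <- !is.na(values) & !is.na(groups)
  values <- values[ok]
  groups <- as.factor(as.character(groups[ok]))
  if (nlevels(groups) < 2)
    abort("need at least two groups", class = "airsound_error_input")
  if (length(unique(values)) == 1)
    abort("all values identical: rank test degenerate",
          class = "airsound_error_input")
  kt <- stats::kruskal.test(values, groups)
  tibble::tibble(
    statistic = unname(kt$statistic),
    df = unname(kt$parameter),
    p_value = kt$p.value,
    method = "Kruskal-Wallis rank sum (chi-squared approximation)",
    group_sizes = paste(table(groups), collapse = ",")
  )
}

tertile_assign <- function(v, probs = c(0.3333, 0.6666)) {
  if (length(unique(v)) == 1) {
    warn("metric constant across sites: degenerate tertiles, all assigned tertile 1")
    return(rep(1L, length(v)))
  }
  q <- quantile(v, probs, type = 7, names = FALSE)
  1L + (v > q[1]) + (v > q[2])
}

#' Bivariate tertile classification
#'
#' Assigns each site a PM2.5 tertile and a sound tertile (quantile
#' breaks at 33.33% and 66.66%, linear-interpolation convention; values
#' equal to a break fall in the lower tertile) and the combined 3x3
#' class label used for bivariate hotspot maps.
#'
#' @param site_values Tibble with `site_id`, `pm` (annual mean PM2.5)
#'   and `sound` (site LAeq or median sound level).
#' @return Tibble: `site_id`, `pm`, `sound`, `pm_tertile`,
#'   `sound_tertile`, `class_label` (`"<pm>-<sound>"`).
#' @export
tertile_bivariate_class <- function(site_values) {
  sv <- site_values[stats::complete.cases(site_values[, c("pm", "sound")]), ]
  if (nrow(sv) < 3)
    abort("need >= 3 sites with both metrics", class = "airsound_error_input")
  sv$pm_tertile <- tertile_assign(sv$pm)
  sv$sound_tertile <- tertile_assign(sv$sound)
  sv$class_label <- sprintf("%d-%d", sv$pm_tertile, sv$sound_tertile)
  tibble::as_tibble(sv)
}

#' Hotspot report
#'
#' Lists sites in the top tertile of either metric with both values;
#' co-hotspots are sites in the top tertile of both PM2.5 and sound.
#'
#' @param classes Output of [tertile_bivariate_class()].
#' @return Tibble of hotspot sites, ranked co-hotspots first and then by
#'   PM level, with `pm_hotspot`, `sound_hotspot`, `co_hotspot` flags.
#' @export
hotspot_report <- function(classes) {
  hs <- classes[classes$pm_tertile == 3 | classes$sound_tertile == 3, ]
  hs$pm_hotspot <- hs$pm_tertile == 3
  hs$sound_hotspot <- hs$sound_tertile == 3
  hs$co_hotspot <- hs$pm_hotspot & hs$sound_hotspot
  hs[order(-hs$co_hotspot, -hs$pm), ]
}
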