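# End-to-end orchestration: simulate (or ingest) -> filter lab ->
# sensor calibration -> temporal adjustment -> acoustic metrics ->
# spatial statistics, with deterministic CSV outputs and a run
# manifest.

ts_format <- "%Y-%m-%dT%H:%M:%S"

fmt_ts <- function(x) format(x, ts_format, tz = "UTC")

write_csv_plain <- function(df, path) {
  df <- as.data.frame(df)
  for (cl in names(df)) {
    if (inherits(df[[cl]], "POSIXct")) df[[cl]] <- fmt_ts(df[[cl]])
    if (inherits(df[[cl]], "Date")) df[[cl]] <- format(df[[cl]])
  }
  write.csv(df, path, row.names = FALSE)
}

#' Write a simulated campaign to CSV
#'
#' Writes `sites.csv`, `deployments.csv`, `minutes_pm.csv` (raw sensor
#' stream), `minutes_sound.csv` and `filters.csv` in long format with
#' ISO-8601 timestamps.
#'
#' @param campaign Output of [simulate_campaign()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the vector of paths written.
#' @export
write_campaign <- function(campaign, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    sites = file.path(dir, "sites.csv"),
    deployments = file.path(dir, "deployments.csv"),
    minutes_pm = file.path(dir, "minutes_pm.csv"),
    minutes_sound = file.path(dir, "minutes_sound.csv"),
    filters = file.path(dir, "filters.csv")
  )
  write_csv_plain(campaign$sites, paths["sites"])
  write_csv_plain(campaign$deployments, paths["deployments"])
  write_csv_plain(campaign$pm_raw, paths["minutes_pm"])
  write_csv_plain(campaign$sound, paths["minutes_sound"])
  write_csv_plain(campaign$filters, paths["filters"])
  invisible(paths)
}

#' Read campaign input CSVs
#'
#' Counterpart of [write_campaign()]: reads the five input tables and
#' restores timestamp types.
#'
#' @param dir Directory containing the campaign CSVs.
#' @return List with `sites`, `deployments`, `pm_raw`, `sound`,
#'   `filters`.
#' @export
read_campaign <- function(dir) {
  rd <- function(name) tibble::as_tibble(
    read.csv(file.path(dir, name), stringsAsFactors = FALSE))
  sites <- rd("sites.csv")
  deployments <- rd("deployments.csv")
  deployments$start <- as.POSIXct(deployments$start, ts_format, tz = "UTC")
  pm_raw <- rd("minutes_pm.csv")
  pm_raw$timestamp <- as.POSIXct(pm_raw$timestamp, ts_format, tz = "UTC")
  sound <- rd("minutes_sound.csv")
  sound$timestamp <- as.POSIXct(sound$timestamp, ts_format, tz = "UTC")
  filters <- rd("filters.csv")
  list(sites = sites, deployments = deployments, pm_raw = pm_raw,
       sound = sound, filters = filters)
}

#' Validate campaign input files
#'
#' Schema and referential-integrity checks on the campaign input CSVs:
#' required columns, enumerated values, unique ids, achieved vs planned
#' minutes, non-negative finite PM values, duplicate timestamps within
#' a deployment, and deployment ids resolving across files.
#'
#' @param dir Directory containing the campaign CSVs.
#' @return Tibble of violations (`file`, `row`, `rule`); zero rows when
#'   the inputs are well formed.
#' @export
validate_inputs <- function(dir) {
  v <- list()
  bad <- function(file, row, rule) {
    v[[length(v) + 1L]] <<- tibble::tibble(file = file,
                                           row = as.integer(row),
                                           rule = rule)
  }
  need <- function(df, file, cols) {
    miss <- setdiff(cols, names(df))
    if (length(miss)) {
      bad(file, NA, paste("missing columns:", paste(miss, collapse = ", ")))
      FALSE
    } else TRUE
  }
  inp <- read_campaign(dir)

  if (need(inp$sites, "sites.csv",
           c("site_id", "site_class", "land_use"))) {
    dup <- which(duplicated(inp$sites$site_id))
    for (i in dup) bad("sites.csv", i, "duplicate site_id")
    off <- which(!inp$sites$land_use %in% LAND_USE_LEVELS)
    for (i in off) bad("sites.csv", i,
                       paste("unknown land_use:", inp$sites$land_use[i]))
    offc <- which(!inp$sites$site_class %in% c("fixed", "rotating"))
    for (i in offc) bad("sites.csv", i, "site_class must be fixed/rotating")
  }

  if (need(inp$deployments, "deployments.csv",
           c("deployment_id", "site_id", "season", "start",
             "planned_minutes", "achieved_minutes"))) {
    dup <- which(duplicated(inp$deployments$deployment_id))
    for (i in dup) bad("deployments.csv", i, "duplicate deployment_id")
    offs <- which(!inp$deployments$season %in% SEASONS)
    for (i in offs) bad("deployments.csv", i, "season must be dry/wet")
    over <- which(inp$deployments$achieved_minutes >
                    inp$deployments$planned_minutes)
    for (i in over) bad("deployments.csv", i,
                        "achieved_minutes exceeds planned_minutes")
    orph <- which(!inp$deployments$site_id %in% inp$sites$site_id)
    for (i in orph) bad("deployments.csv", i, "site_id not in sites.csv")
  }

  check_minutes <- function(df, file, non_negative) {
    if (!need(df, file, c("deployment_id", "timestamp", "value"))) return()
    key <- paste(df$deployment_id, df$timestamp)
    dup <- which(duplicated(key))
    for (i in dup) bad(file, i,
                       paste("duplicate timestamp in deployment",
                             df$deployment_id[i]))
    nf <- which(!is.finite(df$value))
    for (i in nf) bad(file, i, "non-finite value")
    if (non_negative) {
      neg <- which(df$value < 0)
      for (i in neg) bad(file, i, "negative PM value")
    }
    orph <- which(!df$deployment_id %in% inp$deployments$deployment_id)
    for (i in unique(df$deployment_id[orph]))
      bad(file, NA, paste("deployment_id not in deployments.csv:", i))
  }
  check_minutes(inp$pm_raw, "minutes_pm.csv", non_negative = TRUE)
  check_minutes(inp$sound, "minutes_sound.csv", non_negative = FALSE)

  if (need(inp$filters, "filters.csv",
           c("filter_id", "deployment_id", "season", "pre_mass_1",
             "post_mass_1", "flow_rate", "duty_cycle", "is_blank"))) {
    orph <- which(!inp$filters$deployment_id %in%
                    inp$deployments$deployment_id)
    for (i in orph) bad("filters.csv", i,
                        "deployment_id not in deployments.csv")
  }

  if (length(v)) dplyr::bind_rows(v) else
    tibble::tibble(file = character(), row = integer(), rule = character())
}

try_stage <- function(expr, stage, log) {
  tryCatch(expr, error = function(e) {
    log(sprintf("stage %s skipped: %s", stage, conditionMessage(e)))
    NULL
  })
}

#' Run the full campaign analysis
#'
#' Executes the end-to-end chain: simulate the campaign (or ingest user
#' CSVs), process filters, fit and apply season-specific sensor
#' corrections, apply the completeness filter, compute and apply weekly
#' temporal adjustment factors for PM2.5 and BC, build seasonal, annual
#' and grouped exposure summaries, compute sound metrics and guideline
#' exceedances, and run the spatial statistics (Spearman matrix,
#' Kruskal-Wallis land-use tests, bivariate tertile classes, hotspots,
#' day-of-week contrast). All artifacts are written as CSV together with
#' a JSON run manifest; re-running with the same config and seed
#' reproduces identical files.
#'
#' @param config A [campaign_config()].
#' @param out_dir Output directory, or `NULL` to skip writing.
#' @param seed Optional integer overriding `config$seed`.
#' @param input_dir Optional directory of campaign CSVs; when given the
#'   simulation stage is skipped and the files are ingested instead.
#' @return (Invisibly) a list with all intermediate and final tables
#'   plus `manifest`.
#' @export
run_campaign <- function(config = campaign_config(), out_dir = NULL,
                         seed = NULL, input_dir = NULL) {
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
  }
  log_lines <- character()
  log <- function(msg) {
    log_lines <<- c(log_lines, sprintf("[%s] %s", "airsound", msg))
    message(msg)
  }

  if (is.null(input_dir)) {
    log(sprintf("simulating campaign (seed %d)", config$seed))
    campaign <- simulate_campaign(config)
  } else {
    log(sprintf("ingesting campaign from %s (simulation skipped)", input_dir))
    viol <- validate_inputs(input_dir)
    if (nrow(viol))
      abort(paste0("input validation failed: ",
                   paste(sprintf("%s[%s]: %s", viol$file, viol$row,
                                 viol$rule), collapse = "; ")),
            class = "airsound_error_validation")
    inp <- read_campaign(input_dir)
    campaign <- list(config = config, sites = inp$sites,
                     deployments = inp$deployments, pm_true = NULL,
                     pm_raw = inp$pm_raw, filters = inp$filters,
                     sound = inp$sound)
  }
  sites <- campaign$sites
  deployments <- campaign$deployments
  season_starts <- as.Date(vapply(config$seasons, function(s)
    format(s$start), character(1)))

  log("filter lab: processing gravimetric filters")
  grav <- process_filters(campaign$filters, deployments)

  log("sensor calibration")
  pairs <- build_pairs(campaign$pm_raw, grav, deployments, sites)
  models <- fit_campaign_models(pairs)
  linearity <- lapply(intersect(SEASONS, unique(pairs$season)), function(s) {
    p <- pairs[pairs$season == s & pairs$site_group == "general", ]
    rep <- try_stage(check_linearity(p), paste0("linearity_", s), log)
    if (!is.null(rep)) c(season = s, rep)
  })
  linearity <- linearity[!vapply(linearity, is.null, logical(1))]
  corrected <- apply_campaign_models(campaign$pm_raw, models, sites)

  log("completeness filter (PM)")
  cf_pm <- completeness_filter(deployments, corrected, config$completeness)
  daily <- daily_means(cf_pm$minutes)
  dep_weeks <- deployment_week(deployments, season_starts)

  log("temporal adjustment")
  hr_sites <- sites$site_id[sites$high_range_flag]
  fixed_sites <- sites$site_id[sites$site_class == "fixed"]
  adj_daily <- list(); adj_bc <- list(); taf_tables <- list()
  bc_dep <- dplyr::inner_join(
    grav[!is.na(grav$bc_conc), c("deployment_id", "bc_conc")],
    deployments[, c("deployment_id", "site_id", "season", "start",
                    "achieved_minutes")],
    by = "deployment_id")
  bc_dep$day_date <- as.Date(bc_dep$start + 30 * bc_dep$achieved_minutes,
                             tz = "UTC")
  for (s in SEASONS) {
    fixed_daily <- daily[daily$season == s & daily$site_id %in% fixed_sites, ]
    if (!nrow(fixed_daily)) next
    wk_tbl <- weekly_reference_table(fixed_daily, season_starts[[s]],
                                     exclude_sites = hr_sites)
    taf_pm <- compute_taf(wk_tbl, season = s, pollutant = "pm25")
    taf_tables[[paste0("pm25.", s)]] <- taf_pm
    adj_daily[[s]] <- apply_taf(daily[daily$season == s, ], taf_pm,
                                dep_weeks,
                                cols = c("value", "day_value", "night_value"))

    bcs <- bc_dep[bc_dep$season == s, ]
    bcf <- bcs[bcs$site_id %in% setdiff(fixed_sites, hr_sites), ]
    if (nrow(bcf)) {
      bc_ref <- bcf[, c("site_id", "day_date")]
      bc_ref$value <- bcf$bc_conc
      wk_bc <- weekly_reference_table(bc_ref, season_starts[[s]])
      taf_bc <- compute_taf(wk_bc, season = s, pollutant = "bc")
      taf_tables[[paste0("bc.", s)]] <- taf_bc
      adj_bc[[s]] <- try_stage(
        apply_taf(bcs, taf_bc, dep_weeks, cols = "bc_conc"),
        paste0("bc_taf_", s), log)
      if (is.null(adj_bc[[s]])) adj_bc[[s]] <- bcs
    }
  }
  adj_daily <- dplyr::bind_rows(adj_daily)
  adj_bc <- dplyr::bind_rows(adj_bc)

  log("seasonal/annual/grouped summaries")
  seasonal <- seasonal_site_mean(adj_daily,
                                 if (nrow(adj_bc)) adj_bc else NULL)
  annual <- annual_site_mean(seasonal)
  group_tables <- list(
    seasonal_by_land_use = group_summary(
      seasonal, sites, "land_use",
      cols = c("pm_mean", "pm_day_mean", "pm_night_mean", "bc_mean",
               "bc_pm_ratio")),
    seasonal_by_site_class = group_summary(
      seasonal, sites, "site_class",
      cols = c("pm_mean", "pm_day_mean", "pm_night_mean", "bc_mean",
               "bc_pm_ratio")),
    annual_by_land_use = group_summary(annual, sites, "land_use",
                                       cols = c("pm_annual", "bc_annual")),
    annual_by_site_class = group_summary(annual, sites, "site_class",
                                         cols = c("pm_annual", "bc_annual"))
  )

  log("acoustic metrics")
  sound_dep <- deployments[deployments$has_sound, ]
  sound_metrics <- NULL; sound_groups <- NULL; guideline_report <- NULL
  cf_sound <- NULL; diurnal <- NULL
  if (nrow(campaign$sound)) {
    cf_sound <- completeness_filter(sound_dep, campaign$sound,
                                    config$completeness)
    sound_metrics <- sound_site_metrics(cf_sound$minutes)
    sound_groups <- dplyr::bind_rows(
      land_use = sound_group_summary(sound_metrics, sites, "land_use"),
      site_class = sound_group_summary(sound_metrics, sites, "site_class"),
      .id = "grouping")
    guideline_report <- guideline_exceedance(
      cf_sound$minutes, sound_metrics, sites,
      pm_daily = adj_daily)
    diurnal <- dplyr::bind_rows(
      sound = diurnal_profile(cf_sound$minutes, "median"),
      pm_dry = try_stage(diurnal_profile(
        cf_pm$minutes[cf_pm$minutes$season == "dry", ], "mean"),
        "diurnal_pm_dry", log),
      pm_wet = try_stage(diurnal_profile(
        cf_pm$minutes[cf_pm$minutes$season == "wet", ], "mean"),
        "diurnal_pm_wet", log),
      .id = "series")
  }

  log("spatial statistics")
  site_air <- annual
  site_air$bc_pm_ratio <- 100 * site_air$bc_annual / site_air$pm_annual
  spatial <- list()
  if (!is.null(sound_metrics)) {
    site_all <- dplyr::inner_join(
      site_air, sound_metrics[, c("site_id", "laeq", "ir")], by = "site_id")
    spatial$spearman <- try_stage(spearman_matrix(
      site_all[, c("pm_annual", "bc_annual", "bc_pm_ratio", "laeq", "ir")]),
      "spearman", log)
    spatial$classes <- try_stage(tertile_bivariate_class(
      tibble::tibble(site_id = site_all$site_id, pm = site_all$pm_annual,
                     sound = site_all$laeq)), "tertiles", log)
    if (!is.null(spatial$classes))
      spatial$hotspots <- hotspot_report(spatial$classes)
  }
  kw <- list()
  lu_of <- function(ids) sites$land_use[match(ids, sites$site_id)]
  for (s in SEASONS) {
    ss <- seasonal[seasonal$season == s, ]
    kw[[paste0("pm_", s)]] <- try_stage(
      kruskal_wallis(ss$pm_mean, lu_of(ss$site_id)),
      paste0("kw_pm_", s), log)
  }
  if (!is.null(sound_metrics)) {
    kw$laeq <- try_stage(
      kruskal_wallis(sound_metrics$laeq, lu_of(sound_metrics$site_id)),
      "kw_laeq", log)
    kw$ir <- try_stage(
      kruskal_wallis(sound_metrics$ir, lu_of(sound_metrics$site_id)),
      "kw_ir", log)
  }
  spatial$tests <- dplyr::bind_rows(kw[!vapply(kw, is.null, logical(1))],
                                    .id = "contrast")
  spatial$weekday <- try_stage(day_of_week_contrast(adj_daily),
                               "weekday_contrast", log)

  results <- list(
    config = config, sites = sites, deployments = deployments,
    gravimetric = grav, pairs = pairs, models = models,
    linearity = linearity, corrected = corrected,
    retention_pm = cf_pm$report,
    retention_sound = if (!is.null(cf_sound)) cf_sound$report,
    taf_tables = taf_tables, adjusted_daily = adj_daily,
    adjusted_bc = adj_bc, seasonal = seasonal, annual = annual,
    group_tables = group_tables, sound_metrics = sound_metrics,
    sound_groups = sound_groups, guideline_report = guideline_report,
    diurnal = diurnal, spatial = spatial
  )

  if (!is.null(out_dir)) {
    results$manifest <- write_run_outputs(results, campaign, out_dir,
                                          log_lines)
    log(sprintf("outputs written to %s", out_dir))
  }
  invisible(results)
}

model_table <- function(models) {
  dplyr::bind_rows(lapply(models, function(m)
    tibble::tibble(season = m$season, site_group = m$site_group,
                   intercept = m$intercept, slope = m$slope,
                   n_pairs = m$n_pairs, r_squared = m$r_squared,
                   rmse = m$rmse)))
}

taf_export <- function(taf_tables) {
  dplyr::bind_rows(lapply(names(taf_tables), function(k) {
    t <- taf_tables[[k]]
    tibble::tibble(pollutant = attr(t, "pollutant"),
                   season = attr(t, "season"),
                   week = t$week, ref_mean = t$ref_mean,
                   n_days = t$n_days, taf = t$taf,
                   seasonal_reference_mean =
                     attr(t, "seasonal_reference_mean"))
  }))
}

write_run_outputs <- function(results, campaign, out_dir, log_lines) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  inputs_dir <- file.path(out_dir, "inputs")
  write_campaign(campaign, inputs_dir)

  out <- function(df, name) {
    if (is.null(df) || (is.data.frame(df) && !nrow(df))) return(NULL)
    write_csv_plain(df, file.path(out_dir, name))
    name
  }
  written <- c(
    out(results$gravimetric, "gravimetric_results.csv"),
    out(model_table(results$models), "calibration_models.csv"),
    out(results$pairs, "calibration_pairs.csv"),
    out(results$retention_pm, "retention_report_pm.csv"),
    out(results$retention_sound, "retention_report_sound.csv"),
    out(taf_export(results$taf_tables), "taf_table.csv"),
    out(results$seasonal, "seasonal_summary.csv"),
    out(results$annual, "annual_summary.csv"),
    out(dplyr::bind_rows(results$group_tables, .id = "table"),
        "group_summary.csv"),
    out(results$sound_metrics, "sound_metrics.csv"),
    out(results$sound_groups, "sound_group_summary.csv"),
    out(results$diurnal, "diurnal_profiles.csv"),
    out(results$spatial$tests, "tests.csv"),
    out(results$spatial$classes, "bivariate_classes.csv"),
    out(results$spatial$hotspots, "hotspots.csv")
  )
  if (!is.null(results$guideline_report)) {
    written <- c(written,
      out(results$guideline_report$minutes_below, "guideline_minutes.csv"),
      out(results$guideline_report$site_flags, "guideline_site_flags.csv"))
  }
  if (!is.null(results$spatial$spearman)) {
    m <- as.data.frame(results$spatial$spearman)
    m <- cbind(metric = rownames(m), m)
    write_csv_plain(m, file.path(out_dir, "correlation_matrix.csv"))
    written <- c(written, "correlation_matrix.csv")
  }
  if (length(results$linearity)) {
    lines <- vapply(results$linearity, function(l)
      sprintf(paste0("season %s: RMSE linear %.3f, flexible %.3f, ",
                     "improvement %.1f%%, nonlinear: %s (n = %d)"),
              l$season, l$rmse_linear, l$rmse_flexible,
              100 * l$improvement, l$nonlinear, l$n_pairs), character(1))
    writeLines(lines, file.path(out_dir, "linearity_report.txt"))
    written <- c(written, "linearity_report.txt")
  }

  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(config_to_list(results$config), cfg_path)

  inv_files <- c(file.path("inputs", basename(list.files(inputs_dir))),
                 written, "config.yaml")
  inv_paths <- file.path(out_dir, inv_files)
  inventory <- tibble::tibble(
    file = inv_files,
    md5 = unname(tools::md5sum(inv_paths))
  )
  manifest <- list(
    package_version = as.character(utils::packageVersion("airsound")),
    seed = results$config$seed,
    config_md5 = unname(tools::md5sum(cfg_path)),
    n_sites = nrow(results$sites),
    n_deployments = nrow(results$deployments),
    retained_days_pm = sum(results$retention_pm$retained_days),
    retained_days_sound = if (!is.null(results$retention_sound))
      sum(results$retention_sound$retained_days) else 0L,
    n_floored_filters = sum(grepl("floored", results$gravimetric$qc_flags)),
    files = inventory
  )
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  writeLines(log_lines, file.path(out_dir, "run.log"))
  manifest
}

config_to_list <- function(config) {
  cfg <- unclass(config)
  cfg$seasons <- lapply(cfg$seasons, function(s)
    list(start = format(s$start), end = format(s$end)))
  lapply(cfg, function(x) if (is.numeric(x) || is.character(x) ||
                              is.logical(x)) {
    if (!is.null(names(x))) as.list(x) else x
  } else x)
}

#' Read a campaign configuration from a YAML file
#'
#' Keys mirror the arguments of [campaign_config()]; absent keys keep
#' their defaults.
#'
#' @param path Path to a YAML config file.
#' @return A [campaign_config()].
#' @export
read_campaign_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(campaign_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    abort(paste("unknown config keys:", paste(unknown, collapse = ", ")),
          class = "airsound_error_config")
  args <- raw[intersect(names(raw), known)]
  vecs <- c("weekly_trend", "diurnal_night_day", "land_use_multipliers",
            "land_use_proportions", "sensor_bias", "mass_blank",
            "atn_blank", "bc_fraction", "sound_background")
  for (k in intersect(names(args), vecs)) args[[k]] <- unlist(args[[k]])
  if ("seasons" %in% names(args)) {
    args$seasons <- lapply(args$seasons, function(s)
      list(start = as.Date(s$start), end = as.Date(s$end)))
  }
  do.call(campaign_config, args)
}
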