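fake_daily <- function(site_id, dates, values, season = "dry",
                       deployment_id = NULL) {
  tibble::tibble(
    deployment_id = deployment_id %||% paste0("D_", site_id),
    site_id = site_id, season = season,
    measurement_day = seq_along(dates),
    day_date = as.Date(dates),
    day_value = values, night_value = values, value = values,
    n_minutes = 1440L
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("weekly reference mean pools fixed sites and the external monitor", {
  start <- as.Date("2023-01-18")
  d <- fake_daily("S001", start + 0:6, rep(100, 7))
  expect_equal(weekly_reference_mean(d, 1, start), 100)

  # two fixed sites pooled to 120, external at 80 -> equal-weight 100
  d2 <- rbind(fake_daily("S001", start + 0:6, rep(110, 7)),
              fake_daily("S002", start + 0:6, rep(130, 7)))
  ext <- tibble::tibble(day_date = start + 0:6, value = 80)
  expect_equal(weekly_reference_mean(d2, 1, start), 120)
  expect_equal(weekly_reference_mean(d2, 1, start, external_daily = ext), 100)

  # a week with only excluded-site data is missing
  expect_error(weekly_reference_mean(d, 1, start, exclude_sites = "S001"),
               class = "airsound_error_missing_week")
})

test_that("TAF is the weekly-to-seasonal ratio and averages to one", {
  wk <- tibble::tibble(week = 1:3, ref_mean = c(100, 200, 50),
                       n_days = c(7L, 7L, 7L))
  taf <- compute_taf(wk, seasonal_reference_mean = 100)
  expect_equal(taf$taf, c(1, 2, 0.5))
  expect_error(compute_taf(wk, seasonal_reference_mean = 0),
               class = "airsound_error_input")

  taf_auto <- compute_taf(wk)
  w_mean <- sum(taf_auto$taf * wk$n_days) / sum(wk$n_days)
  expect_equal(w_mean, 1, tolerance = 1e-9)

  # uneven durations still average to one under duration weighting
  wk2 <- tibble::tibble(week = 1:3, ref_mean = c(80, 150, 90),
                        n_days = c(7L, 3L, 5L))
  taf2 <- compute_taf(wk2)
  expect_equal(sum(taf2$taf * wk2$n_days) / sum(wk2$n_days), 1,
               tolerance = 1e-9)
})

test_that("TAF lookup interpolates interior weeks and errors at edges", {
  taf <- compute_taf(tibble::tibble(week = c(1, 3), ref_mean = c(100, 200),
                                    n_days = c(7L, 7L)),
                     seasonal_reference_mean = 100)
  expect_equal(taf_for_week(taf, 2), 1.5)
  expect_error(taf_for_week(taf, 4), class = "airsound_error_missing_week")
})

test_that("applying the TAF divides by the deployment week's factor", {
  taf <- compute_taf(tibble::tibble(week = 1:2, ref_mean = c(200, 100),
                                    n_days = c(7L, 7L)),
                     seasonal_reference_mean = 100)
  values <- tibble::tibble(deployment_id = c("D1", "D2"),
                           value = c(150, 150))
  weeks <- tibble::tibble(deployment_id = c("D1", "D2"),
                          season = "dry", week = c(1L, 2L))
  adj <- apply_taf(values, taf, weeks)
  expect_equal(adj$value, c(75, 150))
  expect_error(apply_taf(tibble::tibble(deployment_id = "DX", value = 1),
                         taf, weeks),
               class = "airsound_error_input")
})

test_that("adjustment is scale-equivariant", {
  start <- as.Date("2023-01-18")
  set.seed(9)
  d <- rbind(
    fake_daily("S001", start + 0:13, 100 * exp(rnorm(14, 0, 0.2))),
    fake_daily("S002", start + 0:13, 120 * exp(rnorm(14, 0, 0.2))))
  build_adj <- function(daily) {
    wk <- airsound:::weekly_reference_table(daily, start)
    taf <- compute_taf(wk)
    weeks <- tibble::tibble(
      deployment_id = unique(daily$deployment_id), season = "dry",
      week = 1L)
    # one-week deployments: adjust by each day's own week instead
    daily$week <- week_index(daily$day_date, start)
    daily$adj <- daily$value / taf_for_week(taf, daily$week)
    daily$adj
  }
  a1 <- build_adj(d)
  d3 <- d; d3$value <- 3 * d3$value
  expect_equal(build_adj(d3), 3 * a1, tolerance = 1e-12)
})

test_that("seasonal and annual site summaries use the stated arithmetic", {
  start <- as.Date("2023-01-18")
  one <- fake_daily("S001", start, 100)
  s1 <- seasonal_site_mean(one)
  expect_equal(s1$pm_mean, 100)
  expect_equal(s1$pm_sd, NA_real_)

  two <- fake_daily("S001", start + 0:1, c(80, 120))
  s2 <- seasonal_site_mean(two)
  expect_equal(s2$pm_mean, 100)
  expect_equal(s2$pm_sd, sd(c(80, 120)))
  expect_equal(s2$pm_sd, 28.28, tolerance = 1e-3)

  # day/night windows separated from minute data
  ts <- as.POSIXct("2023-01-18 00:00:00", tz = "UTC") + 60 * 0:1439
  mins <- tibble::tibble(
    deployment_id = "D1", site_id = "S001", season = "dry",
    timestamp = ts, value = ifelse(is_day_minute(ts), 100, 200),
    measurement_day = 1L)
  dm <- daily_means(mins)
  expect_equal(dm$day_value, 100)
  expect_equal(dm$night_value, 200)
  expect_equal(dm$value, mean(mins$value))

  seas <- tibble::tibble(site_id = "S001", season = c("dry", "wet"),
                         pm_mean = c(195, 53.5), bc_mean = c(13.5, 2.88))
  ann <- annual_site_mean(seas)
  expect_equal(ann$pm_annual, 124.25)
  expect_equal(ann$seasons_present, "dry,wet")
  single <- annual_site_mean(seas[1, ])
  expect_equal(single$pm_annual, 195)
})

test_that("group summaries compute per-category means and SDs", {
  sites <- tibble::tibble(site_id = c("S1", "S2", "S3"),
                          site_class = c("fixed", "fixed", "rotating"),
                          land_use = c("residential", "residential", "gbo"))
  vals <- tibble::tibble(site_id = c("S1", "S2", "S3"),
                         pm_annual = c(100, 140, 90))
  g <- group_summary(vals, sites, "land_use", cols = "pm_annual")
  res <- g[g$land_use == "residential", ]
  expect_equal(res$pm_annual_mean, 120)
  expect_equal(res$pm_annual_sd, 28.28, tolerance = 1e-3)
  gbo <- g[g$land_use == "gbo", ]
  expect_true(is.na(gbo$pm_annual_sd))
  g0 <- group_summary(vals, sites, "land_use", cols = "pm_annual",
                      sd_single = "zero")
  expect_equal(g0$pm_annual_sd[g0$land_use == "gbo"], 0)
})

test_that("TAF adjustment removes a shared weekly trend from rotating sites", {
  cfg <- campaign_config(
    n_fixed = 3, n_rotating = 10,
    seasons = list(dry = list(start = "2023-01-18", end = "2023-02-28"),
                   wet = list(start = "2023-07-22", end = "2023-07-28")),
    weekly_trend = c(dry = 0.85, wet = 1),
    sigma_minute = 0.15, sigma_site = 0.1,
    high_range_multiplier = 1, failure_prob = 0, seed = 21)
  sites <- generate_site_network(cfg)
  dep <- simulate_deployment_schedule(sites, cfg)
  dep_dry <- dep[dep$season == "dry", ]
  true <- simulate_true_pm(sites, cfg, dep_dry)
  cf <- completeness_filter(dep_dry, true)
  daily <- daily_means(cf$minutes)

  fixed_ids <- sites$site_id[sites$site_class == "fixed"]
  start <- cfg$seasons$dry$start
  wk <- airsound:::weekly_reference_table(
    daily[daily$site_id %in% fixed_ids, ], start)
  taf <- compute_taf(wk, season = "dry")
  weeks <- deployment_week(dep_dry, c(dry = start, wet = cfg$seasons$wet$start))
  adj <- apply_taf(daily, taf, weeks)

  rot <- sites[sites$site_class == "rotating", ]
  truth <- expected_site_mean(rot, "dry", cfg, conditional = TRUE)
  est <- function(d) {
    m <- tapply(d$value[d$site_id %in% rot$site_id],
                d$site_id[d$site_id %in% rot$site_id], mean)
    m[rot$site_id]
  }
  rmse <- function(e) sqrt(mean((e - truth)^2))
  expect_lt(rmse(est(adj)), rmse(est(daily)))
})

test_that("trend-free campaigns are essentially unchanged by adjustment", {
  cfg <- campaign_config(
    n_fixed = 3, n_rotating = 6,
    seasons = list(dry = list(start = "2023-01-18", end = "2023-02-14"),
                   wet = list(start = "2023-07-22", end = "2023-07-28")),
    weekly_trend = c(dry = 1, wet = 1),
    sigma_minute = 0.1, sigma_site = 0.1,
    high_range_multiplier = 1, failure_prob = 0, seed = 4)
  sites <- generate_site_network(cfg)
  dep <- simulate_deployment_schedule(sites, cfg)
  dep_dry <- dep[dep$season == "dry", ]
  true <- simulate_true_pm(sites, cfg, dep_dry)
  cf <- completeness_filter(dep_dry, true)
  daily <- daily_means(cf$minutes)
  fixed_ids <- sites$site_id[sites$site_class == "fixed"]
  start <- cfg$seasons$dry$start
  taf <- compute_taf(airsound:::weekly_reference_table(
    daily[daily$site_id %in% fixed_ids, ], start), season = "dry")
  weeks <- deployment_week(dep_dry, c(dry = start,
                                      wet = cfg$seasons$wet$start))
  adj <- apply_taf(daily, taf, weeks)
  expect_equal(mean(adj$value), mean(daily$value), tolerance = 0.02)
  expect_true(all(abs(taf$taf - 1) < 0.05))
})
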