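test_that("completeness filter flags shortfalls and slices 24-h days", {
  dep <- tibble::tibble(
    deployment_id = c("D1", "D2"), site_id = c("S1", "S2"),
    season = "dry",
    start = as.POSIXct("2023-01-18 10:00:00", tz = "UTC"),
    planned_minutes = 4320L, achieved_minutes = c(3780L, 3600L),
    has_pm_sensor = TRUE, has_gravimetric = TRUE, has_sound = FALSE)
  mins <- dplyr::bind_rows(lapply(1:2, function(i)
    minute_tibble(rep(100, dep$achieved_minutes[i]),
                  start = dep$start[1],
                  deployment_id = dep$deployment_id[i],
                  site_id = dep$site_id[i])))
  cf <- completeness_filter(dep, mins)
  expect_equal(cf$report$achieved_within_10h, c(TRUE, FALSE))
  # 3780 min = 2 full days + 900 leftover; 3600 = 2 full days + 720
  expect_equal(cf$report$retained_days, c(2L, 2L))
  expect_true(all(table(cf$minutes$deployment_id,
                        cf$minutes$measurement_day) >= 0.8 * 1440))

  orphan <- minute_tibble(rep(1, 10), deployment_id = "ZZ")
  expect_error(completeness_filter(dep, orphan),
               class = "airsound_error_input")
})

test_that("no retained day falls below the completeness fraction", {
  set.seed(5)
  for (i in 1:10) {
    n <- sample(1440:4320, 1)
    dep <- tibble::tibble(
      deployment_id = "D1", site_id = "S1", season = "dry",
      start = as.POSIXct("2023-01-18 00:00:00", tz = "UTC"),
      planned_minutes = 4320L, achieved_minutes = n,
      has_pm_sensor = TRUE, has_gravimetric = TRUE, has_sound = FALSE)
    m <- minute_tibble(rep(1, n), deployment_id = "D1", site_id = "S1")
    m <- m[sort(sample(n, round(0.85 * n))), ] # random within-record gaps
    cf <- completeness_filter(dep, m, completeness = 0.8)
    if (nrow(cf$minutes)) {
      counts <- table(cf$minutes$measurement_day)
      expect_true(all(counts >= 0.8 * 1440))
    }
  }
})

test_that("weekday contrasts use cluster-robust errors", {
  d0 <- tibble::tibble(
    value = rep(5, 12), site_id = rep(c("A", "B", "C"), each = 4),
    day_date = rep(as.Date("2023-01-16") + 0:3, 3))
  r0 <- day_of_week_contrast(d0)
  expect_true(all(abs(r0$contrasts$estimate[-1]) < 1e-12))
  expect_true(all(r0$contrasts$se_cluster < 1e-8))

  # two weekdays, two sites: coefficient equals the weekday mean gap
  d2 <- tibble::tibble(
    value = c(10, 12, 20, 26),
    site_id = c("A", "B", "A", "B"),
    day_date = as.Date(c("2023-01-16", "2023-01-16",
                         "2023-01-17", "2023-01-17")))
  r2 <- day_of_week_contrast(d2, ref = "Mon")
  tue <- r2$contrasts[r2$contrasts$term == "Tue", ]
  expect_equal(tue$estimate, mean(c(20, 26)) - mean(c(10, 12)))

  expect_error(day_of_week_contrast(
    dplyr::mutate(d2, site_id = "A")), class = "airsound_error_input")
})

test_that("singleton clusters reduce CR1 to the HC1 oracle", {
  set.seed(11)
  n <- 40
  d <- tibble::tibble(
    value = rnorm(n, 50, 10),
    site_id = sprintf("S%02d", 1:n), # one observation per cluster
    day_date = as.Date("2023-01-16") + (0:(n - 1)) %% 7)
  r <- day_of_week_contrast(d)

  # independent HC1 oracle from the regression design matrix
  wd <- c("Sun", "Mon", "Tue", "Wed", "Thu", "Fri",
          "Sat")[as.POSIXlt(as.POSIXct(as.character(d$day_date),
                                       tz = "UTC"))$wday + 1]
  f <- factor(wd, levels = c("Mon", setdiff(c("Sun", "Mon", "Tue", "Wed",
                                              "Thu", "Fri", "Sat"), "Mon")))
  f <- droplevels(f)
  X <- model.matrix(~f)
  fit <- lm(d$value ~ f)
  u <- residuals(fit)
  bread <- solve(crossprod(X))
  meat <- crossprod(X * u)
  hc0 <- bread %*% meat %*% bread
  hc1 <- hc0 * n / (n - ncol(X))
  se_oracle <- unname(sqrt(diag(hc1)))
  expect_equal(r$contrasts$se_cluster, se_oracle, tolerance = 1e-6)
})

test_that("Spearman matrix matches rank arithmetic and is well-formed", {
  sm <- tibble::tibble(site_id = sprintf("S%d", 1:4),
                       a = c(1, 2, 3, 4), b = c(1, 3, 2, 4),
                       c = c(4, 3, 2, 1))
  m <- spearman_matrix(sm)
  expect_equal(m["a", "b"], 0.8)
  expect_equal(m["a", "a"], 1)
  expect_equal(m["a", "c"], -1)
  expect_equal(m, t(m))
  expect_true(all(m >= -1 & m <= 1))

  # invariant to strictly monotone transforms
  sm2 <- sm; sm2$a <- exp(sm2$a); sm2$b <- sm2$b^3
  expect_equal(spearman_matrix(sm2)["a", "b"], 0.8)

  const <- sm; const$a <- rep(7, 4)
  expect_true(is.na(spearman_matrix(const)["a", "b"]))
  expect_error(spearman_matrix(sm[1:2, ]), class = "airsound_error_input")
})

test_that("Kruskal-Wallis H matches the closed form and its invariances", {
  kw <- kruskal_wallis(c(1, 2, 3, 4), c("g1", "g1", "g2", "g2"))
  expect_equal(kw$statistic, 2.4)
  expect_equal(kw$df, 1)

  perm <- kruskal_wallis(c(3, 4, 1, 2), c("g2", "g2", "g1", "g1"))
  expect_equal(perm$statistic, kw$statistic)

  mono <- kruskal_wallis(exp(c(1, 2, 3, 4)), c("g1", "g1", "g2", "g2"))
  expect_equal(mono$statistic, kw$statistic)

  expect_error(kruskal_wallis(1:4, rep("g1", 4)),
               class = "airsound_error_input")
  expect_error(kruskal_wallis(rep(2, 6), rep(c("a", "b"), 3)),
               class = "airsound_error_input")
})

test_that("Kruskal-Wallis holds its nominal size under the null", {
  set.seed(17)
  reps <- 4000
  p <- numeric(reps)
  for (i in seq_len(reps)) {
    v <- rnorm(16)
    p[i] <- kruskal_wallis(v, rep(c("a", "b"), each = 8))$p_value
  }
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.015)
})

test_that("tertile classification uses 33.33/66.66 quantile breaks", {
  sv <- tibble::tibble(site_id = sprintf("S%d", 1:9),
                       pm = 1:9, sound = 1:9)
  cl <- tertile_bivariate_class(sv)
  expect_equal(as.vector(table(cl$pm_tertile)), c(3, 3, 3))
  expect_true(all(cl$pm_tertile == cl$sound_tertile))
  expect_equal(cl$class_label[cl$site_id == "S9"], "3-3")

  anti <- tibble::tibble(site_id = sprintf("S%d", 1:9),
                         pm = 1:9, sound = 9:1)
  cla <- tertile_bivariate_class(anti)
  expect_true(all(cla$pm_tertile + cla$sound_tertile == 4))

  # invariant to strictly monotone transforms
  mono <- sv; mono$pm <- log(mono$pm); mono$sound <- mono$sound^2
  expect_equal(tertile_bivariate_class(mono)$pm_tertile, cl$pm_tertile)

  flat <- sv; flat$sound <- rep(5, 9)
  expect_warning(clf <- tertile_bivariate_class(flat), "degenerate")
  expect_true(all(clf$sound_tertile == 1))

  expect_error(tertile_bivariate_class(sv[1:2, ]),
               class = "airsound_error_input")
})

test_that("hotspot report surfaces top-tertile and co-hotspot sites", {
  sv <- tibble::tibble(site_id = sprintf("S%d", 1:9),
                       pm = c(1:8, 50), sound = c(9:2, 60))
  cl <- tertile_bivariate_class(sv)
  hs <- hotspot_report(cl)
  expect_true("S9" %in% hs$site_id[hs$co_hotspot])
  expect_true(all(hs$pm_tertile == 3 | hs$sound_tertile == 3))
  expect_equal(hs$site_id[1], "S9") # co-hotspots ranked first

  flat <- tibble::tibble(site_id = sprintf("S%d", 1:4),
                         pm = rep(1, 4), sound = rep(1, 4))
  suppressWarnings(clf <- tertile_bivariate_class(flat))
  expect_equal(nrow(hotspot_report(clf)), 0)
})

test_that("an extreme industrial site emerges as a PM hotspot", {
  cfg <- small_config(seed = 13, high_range_multiplier = 4)
  res <- suppressMessages(run_campaign(cfg))
  hr <- res$sites$site_id[res$sites$high_range_flag]
  hs <- res$spatial$hotspots
  expect_true(hr %in% hs$site_id[hs$pm_hotspot])
})
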