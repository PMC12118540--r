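hourly_axis <- function(n_days, start = "2020-02-01") {
  seq(as.POSIXct(paste(start, "00:00"), tz = "UTC"),
      by = "hour", length.out = 24 * n_days)
}

test_that("event detection finds runs, merges short gaps, sets windows", {
  dt <- hourly_axis(20)
  rain <- data.frame(datetime = dt, rain_mmhr = 0)
  expect_equal(nrow(detect_events(rain)), 0)

  # one 6-hour event starting at day-5 hour 0
  i0 <- 4 * 24 + 1
  rain$rain_mmhr[i0:(i0 + 5)] <- 2
  ev <- detect_events(rain)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$wet_start, dt[i0])
  expect_equal(ev$wet_end, dt[i0 + 5])
  expect_equal(as.numeric(difftime(ev$wet_start, ev$pre_start,
                                   units = "days")), 2)
  expect_equal(as.numeric(difftime(ev$accum_end, ev$wet_end,
                                   units = "days")), 3)

  # a second burst 8 dry hours later merges (< 12 h gap); one 20 h later
  # does not
  rain$rain_mmhr[(i0 + 5 + 9):(i0 + 5 + 11)] <- 1
  j0 <- i0 + 5 + 11 + 21
  rain$rain_mmhr[j0:(j0 + 2)] <- 3
  ev2 <- detect_events(rain)
  expect_equal(nrow(ev2), 2)
  expect_equal(ev2$wet_end[1], dt[i0 + 5 + 11])
  expect_equal(ev2$wet_start[2], dt[j0])

  # sub-threshold drizzle is not wet
  drz <- data.frame(datetime = dt, rain_mmhr = 0.05)
  expect_equal(nrow(detect_events(drz)), 0)
})

test_that("event deltas are window-mean differences with quadrature SD", {
  dt <- hourly_axis(12)
  rain <- data.frame(datetime = dt, rain_mmhr = 0)
  i0 <- 5 * 24 + 1
  rain$rain_mmhr[i0:(i0 + 23)] <- 4 # day 6 fully wet
  ev <- detect_events(rain)
  days <- seq(as.Date("2020-02-01"), by = "day", length.out = 12)
  vals <- c(1, 2, 3, 4, 5, 9, 20, 22, 24, 2, 2, 2)
  ser <- data.frame(date = days, value = vals)
  # pre window: days 4-5 (2 days before wet start); accumulation: days 7-9
  d <- event_deltas(ev[1, ], ser)
  pre <- vals[4:5]; post <- vals[7:9]
  expect_equal(d$delta, mean(post) - mean(pre), tolerance = 1e-12)
  expect_equal(d$sd, sqrt(var(pre) / 2 + var(post) / 3), tolerance = 1e-12)
  expect_equal(c(d$n_pre, d$n_post), c(2L, 3L))
  dw <- event_deltas(ev[1, ], ser, post = "wet")
  expect_equal(dw$delta, vals[6] - mean(pre), tolerance = 1e-12)

  expect_error(event_deltas(ev[1, ], ser[7:12, ]), "no samples in pre")
})

test_that("forced-zero regression matches its closed form", {
  x <- c(1, 2, 3, 5, 8)
  y <- c(2.1, 3.9, 6.3, 9.6, 16.4)
  fit <- regress(x, y, force_zero_intercept = TRUE)
  expect_equal(fit$slope, sum(x * y) / sum(x^2), tolerance = 1e-12)
  expect_equal(fit$intercept, 0)
  expect_equal(fit$r_squared, cor(y, fit$slope * x)^2, tolerance = 1e-12)
  # uncentered definition on request
  fu <- regress(x, y, force_zero_intercept = TRUE, uncentered_r2 = TRUE)
  expect_equal(fu$r_squared, 1 - sum((y - fit$slope * x)^2) / sum(y^2),
               tolerance = 1e-12)
  # exact proportional data
  fe <- suppressWarnings(regress(x, 3 * x, force_zero_intercept = TRUE))
  expect_equal(fe$slope, 3, tolerance = 1e-12)
  expect_equal(fe$r_squared, 1, tolerance = 1e-12)

  expect_error(regress(1, 2), "at least 2")
  expect_error(regress(c(0, 0), c(1, 2), force_zero_intercept = TRUE),
               "all x are 0")
})

test_that("free regression reproduces lm and the strength bands", {
  set.seed(7)
  x <- rnorm(20); y <- 2 + 0.5 * x + rnorm(20, 0, 0.3)
  fit <- regress(x, y)
  lmf <- summary(lm(y ~ x))
  expect_equal(fit$slope, unname(coef(lmf)["x", "Estimate"]))
  expect_equal(fit$r_squared, lmf$r.squared)
  expect_equal(fit$p_value, coef(lmf)["x", "Pr(>|t|)"])
  expect_equal(strength_band(c(0.71, 0.7, 0.4, 0.39, NA)),
               c("strong", "moderate", "moderate", "weak", NA))
})

test_that("tracer correlations pool sites and honor the censor policy", {
  days <- as.Date("2020-02-01") + 0:9
  mk <- function(site, cmp, v, cens = "none") {
    data.frame(site = site, date = days, matrix = "aerosol", compound = cmp,
               value = v, unit = "pg/m3", censor = cens,
               stringsAsFactors = FALSE)
  }
  tr <- c(1, 3, 5, 2, 8, 4, 6, 7, 2, 9)
  samp <- rbind(mk("IB", "benzoylecgonine", tr),
                mk("IB", "methamphetamine", 2 * tr),
                mk("SS", "benzoylecgonine", tr + 1),
                mk("SS", "methamphetamine", 2 * (tr + 1)))
  res <- suppressWarnings(tracer_correlations(samp))
  # exactly proportional -> slope 2, R2 1, pooled over both sites
  expect_equal(res$slope, 2, tolerance = 1e-9)
  expect_equal(res$r_squared, 1, tolerance = 1e-9)
  expect_equal(res$n, 20)

  # a censored pair is excluded under the default policy
  samp2 <- samp
  samp2$censor[samp2$site == "IB" &
                 samp2$compound == "methamphetamine"][1] <- "lt_lod"
  res2 <- suppressWarnings(tracer_correlations(samp2))
  expect_equal(res2$n, 19)
  expect_equal(res2$censored_n, 1)
  res2s <- suppressWarnings(tracer_correlations(samp2, policy = "substitute"))
  expect_equal(res2s$n, 20)

  # site with fully censored tracer is dropped with a warning
  samp3 <- samp
  samp3$censor[samp3$site == "SS" &
                 samp3$compound == "benzoylecgonine"] <- "lt_lod"
  expect_warning(res3 <- withCallingHandlers(
    tracer_correlations(samp3),
    warning = function(w) {
      if (grepl("perfect fit", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }
  ), "site SS")
  expect_equal(res3$n, 10)

  expect_error(tracer_correlations(samp, tracer = "nope"), "not present")
})

test_that("exact Mann-Whitney p matches full enumeration, with ties", {
  cases <- list(
    list(a = c(1.2, 3.4, 2.2, 5.0), b = c(4.1, 6.3, 7.7, 5.5)),
    list(a = c(1, 2, 2, 3), b = c(2, 4, 4, 5, 6)), # heavy ties
    list(a = c(10, 12, 11), b = c(10, 12, 11)),    # identical groups
    list(a = c(0.5, 0.7, 0.9, 1.1, 1.3), b = c(0.6, 0.8, 1.0))
  )
  for (cs in cases) {
    got <- site_compare(cs$a, cs$b)
    expect_equal(got$method, "exact_permutation")
    expect_equal(got$p_value, mw_enumerate_p(cs$a, cs$b), tolerance = 1e-12)
  }
  # complete separation of 4 vs 4: two-sided p = 2/choose(8,4)
  sep <- site_compare(1:4, 11:14)
  expect_equal(sep$p_value, 2 / choose(8, 4), tolerance = 1e-12)
  expect_error(site_compare(1:2, 1:5), "at least 3")
})

test_that("large samples use the tie-corrected normal approximation", {
  set.seed(3)
  a <- rnorm(25); b <- rnorm(25, 0.8)
  got <- site_compare(a, b)
  expect_equal(got$method, "normal_tie_corrected")
  ref <- suppressWarnings(wilcox.test(a, b, correct = TRUE, exact = FALSE))
  expect_equal(got$U, unname(ref$statistic))
  expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
})

test_that("airmass classification applies the strict 75/25 thresholds", {
  # four synthetic days of hourly directions
  mkday <- function(date, dirs) {
    data.frame(datetime = as.POSIXct(paste(date, sprintf("%02d:00", 0:23)),
                                     tz = "UTC"),
               wind_dir_deg = dirs)
  }
  wind <- rbind(
    mkday("2020-02-01", rep(270, 24)),                    # all onshore
    mkday("2020-02-02", rep(90, 24)),                     # all offshore
    mkday("2020-02-03", c(rep(270, 18), rep(90, 6))),     # exactly 75%
    mkday("2020-02-04", c(rep(270, 12), rep(NA, 12)))     # 50% missing
  )
  rain <- data.frame(datetime = wind$datetime, rain_mmhr = 0)
  rain$rain_mmhr[3] <- 1 # one wet hour on day 1
  cls <- classify_airmass(wind, rain)
  expect_equal(cls$wind_class,
               c("onshore", "offshore", "mixed", "unknown"))
  expect_equal(cls$wet, c(TRUE, FALSE, FALSE, FALSE))
})

test_that("daily series extraction filters, orders, and drops censored", {
  cam <- study_campaign(seed = 4)
  s <- daily_series(cam$samples, "IB", "benzoylecgonine", "aerosol")
  expect_equal(s$date, sort(s$date))
  raw <- cam$samples[cam$samples$site == "IB" &
                       cam$samples$compound == "benzoylecgonine" &
                       cam$samples$matrix == "aerosol", ]
  expect_equal(nrow(s), nrow(raw))
  s2 <- daily_series(cam$samples, "IB", "benzoylecgonine", "aerosol",
                     drop_censored = TRUE)
  expect_equal(nrow(s2), sum(raw$censor != "lt_lod"))
})
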