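test_that("configuration invariants are enforced", {
  sites <- default_sites()
  sites$type <- "coastal"
  expect_error(campaign_config(sites = sites), "exactly one river site")
  cmp <- default_compounds()
  cmp$k_a[1] <- -1
  expect_error(campaign_config(compounds = cmp), "positive")
  ev <- data.frame(start_day = 60, duration_h = 6, intensity_mm_h = 1)
  expect_error(campaign_config(n_days = 50, rain_events = ev),
               "cover the longest event")
})

test_that("river flow is an exponential-kernel response to rain", {
  cfg <- campaign_config(rain_events = data.frame(start_day = numeric(0),
                                                  duration_h = numeric(0),
                                                  intensity_mm_h = numeric(0)),
                         n_days = 10)
  rain <- simulate_rain(cfg)
  flow <- simulate_river_flow(rain, 30, 5, 24)
  expect_true(all(flow$flow_mgd == 30)) # no forcing

  # single impulse: discrete convolution oracle and e-folding decay
  rain$rain_mmhr[50] <- 1
  flow <- simulate_river_flow(rain, 30, 5, 24)
  lags <- seq_along(rain$rain_mmhr) - 50
  oracle <- 30 + 5 * ifelse(lags >= 0, exp(-lags / 24), 0)
  expect_equal(flow$flow_mgd, oracle, tolerance = 1e-12)
  anom <- flow$flow_mgd - 30
  expect_equal(anom[50 + 24] / anom[50], exp(-1), tolerance = 1e-12)

  # linearity: doubling rain doubles the anomaly everywhere
  rain2 <- rain
  rain2$rain_mmhr <- 2 * rain$rain_mmhr
  flow2 <- simulate_river_flow(rain2, 30, 5, 24)
  expect_equal(flow2$flow_mgd - 30, 2 * (flow$flow_mgd - 30),
               tolerance = 1e-12)
  expect_true(all(flow$flow_mgd >= 30))

  rain$rain_mmhr[1] <- -1
  expect_error(simulate_river_flow(rain, 30, 5, 24), "non-negative")
  rain$rain_mmhr[1] <- 0
  expect_error(simulate_river_flow(rain, 30, 5, -2), "positive")
})

test_that("noiseless water concentrations are exactly affine in daily flow", {
  cfg <- campaign_config(noise_cv = 0)
  rain <- simulate_rain(cfg)
  flow <- simulate_river_flow(rain, cfg$flow_baseline, cfg$flow_gain,
                              cfg$flow_decay_h)
  water <- simulate_water_concentrations(flow, cfg$sites, cfg$compounds,
                                         noise_cv = 0,
                                         flow_baseline = cfg$flow_baseline)
  ib <- water[water$site == "IB" & water$compound == "benzoylecgonine", ]
  fl <- tapply(flow$flow_mgd, as.Date(flow$datetime, tz = "UTC"), mean)
  fit <- suppressWarnings(regress(as.numeric(fl), ib$value))
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  # designed coefficients recovered exactly
  expect_equal(fit$slope, 0.2 * exp(-2.6 / 15), tolerance = 1e-9)
})

test_that("water gradient: river site dominates the distant site", {
  # generator oracle: the noiseless TJR/SIO median ratio
  cfg0 <- campaign_config(noise_cv = 0)
  cam0 <- simulate_campaign(cfg0)
  w0 <- cam0$water_truth
  med <- function(w, s) median(w$value[w$site == s &
                                         w$compound == "benzoylecgonine"])
  design_ratio <- med(w0, "TJR") / med(w0, "SIO")
  expect_gt(design_ratio, 10)
  for (seed in 1:10) {
    w <- simulate_campaign(campaign_config(seed = seed))$water_truth
    expect_gt(med(w, "TJR") / med(w, "SIO"), design_ratio / 2)
  }
})

test_that("expected water concentration is non-increasing with distance", {
  cfg <- campaign_config(noise_cv = 0)
  w <- simulate_campaign(cfg)$water_truth
  coastal <- cfg$sites[cfg$sites$type == "coastal", ]
  ord <- coastal$id[order(abs(coastal$distance_from_river_km))]
  meds <- vapply(ord, function(s) {
    median(w$value[w$site == s & w$compound == "benzoylecgonine"])
  }, numeric(1))
  expect_true(all(diff(meds) <= 1e-12))
})

test_that("area-source-only compounds show no site gradient", {
  cmp <- default_compounds()
  cmp$coupling[cmp$name == "dibenzylamine"] <- 0
  cfg <- campaign_config(compounds = cmp, noise_cv = 0)
  w <- simulate_campaign(cfg)$water_truth
  d <- w[w$compound == "dibenzylamine" & w$site %in% c("BF", "IB", "SIO"), ]
  expect_equal(length(unique(d$value)), 1) # uniform background
})

test_that("aerosol limiting cases behave as constructed", {
  cam <- analytic_campaign()
  cfg <- cam$config
  # infinite scavenging on an all-rain day leaves only the area source
  rain <- cam$rain
  aero <- simulate_aerosol_concentrations(
    cam$water_truth, cam$ssa_flux, rain, cfg$sites, cfg$compounds,
    scavenge_rate = 1e6, deposition_tau_days = Inf,
    transfer_scale = 0, area_sources = TRUE, noise_cv = 0
  )
  caf <- aero[aero$compound == "caffeine" & aero$site == "IB", ]
  expect_true(all(abs(caf$value - 5) < 1e-9)) # caffeine area source 5 pg/m3

  # zero SSA flux and zero area source: aerosol identically zero
  flux0 <- cam$ssa_flux
  flux0$flux <- 0
  aero0 <- simulate_aerosol_concentrations(
    cam$water_truth, flux0, rain, cfg$sites, cfg$compounds,
    area_sources = FALSE, noise_cv = 0
  )
  expect_true(all(aero0$value == 0))

  # mismatched time axes are rejected
  flux_bad <- cam$ssa_flux[-1, ]
  expect_error(simulate_aerosol_concentrations(
    cam$water_truth, flux_bad, rain, cfg$sites, cfg$compounds
  ), "time axis")
})

test_that("measurement model preserves clean values and censors truth zero", {
  truth <- data.frame(site = "IB", date = as.Date("2020-02-01"),
                      matrix = "water",
                      compound = c("a", "b"), value = c(100, 0),
                      unit = "ng/L", stringsAsFactors = FALSE)
  lods <- data.frame(compound = c("a", "b"), matrix = "water",
                     lod = c(1, 1), loq = c(10 / 3, 10 / 3), unit = "ng/L",
                     stringsAsFactors = FALSE)
  out <- apply_measurement_model(truth, lods, measurement_cv = 0)
  expect_equal(out$value[1], 100)
  expect_equal(out$censor[1], "none")
  expect_equal(out$value[2], 1) # reported at the LOD
  expect_equal(out$censor[2], "lt_lod")
})

test_that("censoring frequency tracks the LOD quantile", {
  # Monte-Carlo oracle: with the LOD at the q-quantile of the truth and
  # small measurement noise, the lt_lod fraction stays within binomial
  # error of q
  q <- 0.1
  n_per <- 200
  hits <- 0L
  total <- 0L
  for (seed in 1:30) {
    truth <- data.frame(site = "IB", date = as.Date("2020-02-01"),
                        matrix = "water", compound = "x",
                        value = with_seed_values(seed, n_per),
                        unit = "ng/L", stringsAsFactors = FALSE)
    lods <- derive_lods(truth, q)
    out <- apply_measurement_model(truth, lods, measurement_cv = 0.02,
                                   seed = seed + 1000)
    hits <- hits + sum(out$censor == "lt_lod")
    total <- total + n_per
  }
  p_hat <- hits / total
  tol <- 4 * sqrt(q * (1 - q) / total) + 0.01 # binomial error + noise blur
  expect_lt(abs(p_hat - q), tol)
})

test_that("identical config and seed give byte-identical campaigns", {
  a <- simulate_campaign(campaign_config(seed = 11))
  b <- simulate_campaign(campaign_config(seed = 11))
  expect_identical(serialize(a$samples, NULL), serialize(b$samples, NULL))
  expect_identical(serialize(a$flow, NULL), serialize(b$flow, NULL))
  c2 <- simulate_campaign(campaign_config(seed = 12))
  expect_false(identical(a$samples$value, c2$samples$value))
})

test_that("campaign round-trips through CSV output", {
  cam <- study_campaign(seed = 3)
  dir <- withr_local_tempdir()
  write_campaign(cam, dir)
  back <- read_samples(file.path(dir, "samples.csv"))
  expect_equal(nrow(back), nrow(cam$samples))
  expect_equal(back$value, cam$samples$value, tolerance = 1e-9)
  expect_true(file.exists(file.path(dir, "config.json")))
})
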