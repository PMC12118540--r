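#' Seeded synthetic sampling campaigns
#'
#' The generator emulates the structure of a coastal water/aerosol sampling
#' campaign around a polluted river mouth: hourly rain drives river flow
#' through an exponential response kernel; daily water concentrations at
#' coastal sites follow flow linearly, attenuated with distance from the
#' river mouth; aerosol concentrations are wet-scavenged during rain and
#' then rebuild in proportion to the sea spray mass flux and the same-day
#' water concentration; a measurement model adds multiplicative lognormal
#' noise and detection-limit censoring. Identical (config, seed) pairs give
#' byte-identical tables.
#'
#' @name synthetic_data
NULL

#' Default site layout
#'
#' One river site and four coastal sites at signed distances (km, north
#' positive) from the river mouth, mirroring a south-to-north sampling
#' transect.
#' @param gradient_scale e-folding distance (km) of the water-concentration
#'   attenuation away from the river mouth.
#' @return data.frame with `id`, `distance_from_river_km`, `type`,
#'   `gradient_scale`.
#' @export
default_sites <- function(gradient_scale = 15) {
  data.frame(
    id = c("BF", "TJR", "IB", "SS", "SIO"),
    distance_from_river_km = c(-2.4, 0, 2.6, 8.7, 36),
    type = c("coastal", "river", "coastal", "coastal", "coastal"),
    gradient_scale = gradient_scale,
    stringsAsFactors = FALSE
  )
}

#' Default compound registry
#'
#' Twelve wastewater-associated compounds with representative (literature
#' order-of-magnitude, not measured) physicochemical constants: log Kow,
#' air and aqueous adsorption coefficients (m), river median concentration
#' (ng/L), an airborne area-source background (pg/m3) for compounds with
#' non-sewage sources, a photochemical e-folding lifetime (days; Inf for
#' photostable compounds), the urinary excretion fraction where relevant,
#' and the river-flow coupling of the near-river coastal water
#' concentration ((ng/L)/MGD before distance attenuation).
#' @return data.frame, one row per compound.
#' @export
default_compounds <- function() {
  data.frame(
    name = c("benzoylecgonine", "caffeine", "carbamazepine", "cocaine",
             "diazinon", "dibenzylamine", "erythromycin", "heroin",
             "imazapyr", "isoxaben", "methamphetamine", "octinoxate"),
    log_kow = c(-1.3, -0.07, 2.45, 2.30, 3.81, 2.9, 3.06, 1.58,
                0.22, 3.94, 2.07, 5.8),
    k_a  = c(1e-4, 1e-4, 1e-4, 1e-4, 2e-4, 2e-4, 1e-4, 1e-4,
             5e-5, 2.5e-4, 1e-4, 1e-1),
    k_aq = c(1e-2, 5e-3, 2e-3, 3e-3, 1e-3, 1.6e-3, 1.5e-3, 4e-3,
             4e-3, 1e-3, 6e-3, 1e-3),
    river_median_conc = c(2000, 5000, 500, 100, 200, 50, 300, 80,
                          400, 100, 1500, 8000),
    area_source_air = c(0, 5, 0, 3, 2, 4, 0, 1, 0, 1.5, 0, 10),
    tau_photo = c(Inf, Inf, Inf, Inf, Inf, Inf, Inf, Inf, Inf, Inf, Inf, 4),
    excretion_fraction = c(0.45, NA, NA, 0.09, NA, NA, NA, NA, NA, NA,
                           NA, NA),
    coupling = c(0.2, 0.5, 0.05, 0.005, 0.02, 0.001, 0.03, 0.008,
                 0.04, 0.01, 0.15, 0.5),
    stringsAsFactors = FALSE
  )
}

#' Default rain-event schedule
#'
#' Five discrete precipitation events of varying duration and intensity
#' over a 50-day campaign, spaced so pre- and accumulation windows do not
#' overlap.
#' @return data.frame with `start_day`, `duration_h`, `intensity_mm_h`.
#' @export
default_rain_events <- function() {
  data.frame(
    start_day = c(6, 14, 22, 31, 40),
    duration_h = c(12, 8, 18, 6, 15),
    intensity_mm_h = c(4, 2.5, 8, 5, 12)
  )
}

#' Build a campaign configuration
#'
#' @param n_days campaign length in days (must cover the longest event
#'   window).
#' @param start first day (Date or string).
#' @param sites site table, see [default_sites()]; exactly one `river` row.
#' @param compounds compound registry, see [default_compounds()].
#' @param rain_events event schedule, see [default_rain_events()].
#' @param seed integer RNG seed; fixed seed implies byte-identical output.
#' @param noise_cv coefficient of variation of the multiplicative lognormal
#'   process noise on water and aerosol concentrations.
#' @param measurement_cv additional multiplicative noise applied by the
#'   measurement model.
#' @param lod_quantile quantile of the generated true concentrations at
#'   which per-compound/matrix detection limits are placed.
#' @param flow_baseline,flow_gain,flow_decay_h river-flow response: base
#'   flow (MGD), gain (MGD per mm of hourly rain) and exponential decay
#'   time (h).
#' @param wind_base,wind_gain,wind_decay_h,wind_diurnal_amp wind model:
#'   background u10 (m/s), storm-wind gain per mm of hourly rain,
#'   storm-wind decay (h), diurnal sea-breeze amplitude (m/s).
#' @param sst_c sea surface temperature (degC, constant).
#' @param scavenge_rate wet-scavenging rate of the airborne pool (per wet
#'   hour).
#' @param deposition_tau_days dry-deposition e-folding residence time of
#'   the airborne pool (days); keeps aerosol levels stationary between
#'   events.
#' @param transfer_scale water-to-air transfer scale at log Kow = 2,
#'   (pg/m3) per ((pg m^-2 day^-1) x (ng/L)).
#' @param transfer_gamma designed exponent of the Kow dependence of the
#'   transfer weight (weight proportional to Kow^gamma).
#' @param aerosol_coupling `"sameday"` (increment uses same-day water) or
#'   `"constant"` (increment uses the site's baseline water concentration;
#'   analytic validation mode in which the post-event aerosol increase is
#'   exactly proportional to integrated SSA flux).
#' @param area_sources logical; include airborne area-source backgrounds.
#' @return object of class `campaign_config`.
#' @export
campaign_config <- function(n_days = 50, start = "2020-01-24",
                            sites = default_sites(),
                            compounds = default_compounds(),
                            rain_events = default_rain_events(),
                            seed = 1,
                            noise_cv = 0.1,
                            measurement_cv = 0.05,
                            lod_quantile = 0.05,
                            flow_baseline = 30, flow_gain = 5,
                            flow_decay_h = 24,
                            wind_base = 4, wind_gain = 0.06,
                            wind_decay_h = 36, wind_diurnal_amp = 1.5,
                            sst_c = 16,
                            scavenge_rate = 0.5,
                            deposition_tau_days = 2,
                            transfer_scale = 1e-10,
                            transfer_gamma = 0.5,
                            aerosol_coupling = c("sameday", "constant"),
                            area_sources = TRUE) {
  aerosol_coupling <- match.arg(aerosol_coupling)
  stopifnot(n_days >= 1, noise_cv >= 0, measurement_cv >= 0,
            lod_quantile >= 0, lod_quantile < 1,
            flow_baseline > 0, flow_decay_h > 0, scavenge_rate >= 0,
            deposition_tau_days > 0)
  if (sum(sites$type == "river") != 1) {
    stop("sites must contain exactly one river site")
  }
  if (any(sites$gradient_scale <= 0)) stop("gradient_scale must be > 0")
  if (any(compounds$k_a <= 0) || any(compounds$k_aq <= 0)) {
    stop("adsorption coefficients must be positive")
  }
  if (any(compounds$river_median_conc < 0)) {
    stop("river_median_conc must be non-negative")
  }
  ef <- compounds$excretion_fraction
  if (any(!is.na(ef) & (ef < 0 | ef > 1))) {
    stop("excretion fractions must lie in [0, 1]")
  }
  if (nrow(rain_events) > 0) {
    last <- max(rain_events$start_day + rain_events$duration_h / 24)
    if (n_days < last) stop("n_days must cover the longest event window")
  }
  structure(list(
    n_days = n_days, start = as.Date(start), sites = sites,
    compounds = compounds, rain_events = rain_events, seed = seed,
    noise_cv = noise_cv, measurement_cv = measurement_cv,
    lod_quantile = lod_quantile,
    flow_baseline = flow_baseline, flow_gain = flow_gain,
    flow_decay_h = flow_decay_h,
    wind_base = wind_base, wind_gain = wind_gain,
    wind_decay_h = wind_decay_h, wind_diurnal_amp = wind_diurnal_amp,
    sst_c = sst_c, scavenge_rate = scavenge_rate,
    deposition_tau_days = deposition_tau_days,
    transfer_scale = transfer_scale, transfer_gamma = transfer_gamma,
    aerosol_coupling = aerosol_coupling, area_sources = area_sources
  ), class = "campaign_config")
}

# internal: hourly POSIXct grid of a campaign
campaign_hours <- function(config) {
  seq(as.POSIXct(paste(config$start, "00:00:00"), tz = "UTC"),
      by = "hour", length.out = config$n_days * 24)
}

#' Hourly rain series from an event schedule
#'
#' @param config a [campaign_config()].
#' @return data.frame `datetime`, `rain_mmhr`.
#' @export
simulate_rain <- function(config) {
  hours <- campaign_hours(config)
  rain <- numeric(length(hours))
  ev <- config$rain_events
  if (nrow(ev) > 0) {
    for (i in seq_len(nrow(ev))) {
      h0 <- round((ev$start_day[i] - 1) * 24) + 1
      idx <- h0:min(h0 + ev$duration_h[i] - 1, length(hours))
      rain[idx] <- rain[idx] + ev$intensity_mm_h[i]
    }
  }
  data.frame(datetime = hours, rain_mmhr = rain)
}

# internal: causal exponential-kernel convolution, unit kernel at lag 0
exp_kernel_response <- function(forcing, decay_steps) {
  a <- exp(-1 / decay_steps)
  out <- numeric(length(forcing))
  acc <- 0
  for (i in seq_along(forcing)) {
    acc <- acc * a + forcing[i]
    out[i] <- acc
  }
  out
}

#' Simulate river flow as an exponential-kernel response to rain
#'
#' flow(t) = baseline + gain * (rain convolved with a causal exponential
#' kernel of the given decay time); strictly >= baseline everywhere, and a
#' single rain impulse decays by a factor e per decay time.
#'
#' @param rain data.frame `datetime`, `rain_mmhr` (hourly, rain >= 0).
#' @param baseline base flow, MGD (> 0).
#' @param gain flow response, MGD per mm of hourly rain.
#' @param decay_time_h exponential decay time, hours (> 0).
#' @return data.frame `datetime`, `flow_mgd`.
#' @export
simulate_river_flow <- function(rain, baseline, gain, decay_time_h) {
  stopifnot(all(c("datetime", "rain_mmhr") %in% names(rain)))
  if (any(rain$rain_mmhr < 0)) stop("rain must be non-negative")
  if (decay_time_h <= 0) stop("decay_time_h must be positive")
  if (baseline <= 0) stop("baseline flow must be positive")
  anomaly <- gain * exp_kernel_response(rain$rain_mmhr, decay_time_h)
  data.frame(datetime = rain$datetime, flow_mgd = baseline + anomaly)
}

#' Simulate hourly meteorology (wind speed, direction, SST)
#'
#' Wind speed is a background plus a diurnal sea-breeze cycle plus a
#' storm-wind response to rain (same exponential-kernel form as the flow
#' model). Wind direction follows a day/night onshore/offshore sea-breeze
#' pattern with directional noise, so most 23-h sampling days are mixed.
#'
#' @param config a [campaign_config()].
#' @param rain output of [simulate_rain()] (regenerated if missing).
#' @return data.frame `datetime`, `u10_ms`, `sst_c`, `rain_mmhr`,
#'   `wind_dir_deg`.
#' @export
simulate_met <- function(config, rain = simulate_rain(config)) {
  hours <- rain$datetime
  hod <- as.integer(format(hours, "%H"))
  diurnal <- config$wind_diurnal_amp * sin(2 * pi * (hod - 6) / 24)
  storm <- config$wind_gain *
    exp_kernel_response(rain$rain_mmhr, config$wind_decay_h)
  u10 <- pmax(config$wind_base + diurnal + storm, 0.2)
  dir <- with_seed(stage_seed(config$seed, "wind"), {
    base_dir <- ifelse(hod >= 10 & hod < 19, 270, 90) # sea breeze cycle
    base_dir <- ifelse(storm > 1, 250, base_dir)       # storms blow onshore
    (base_dir + stats::rnorm(length(hours), 0, 40)) %% 360
  })
  data.frame(datetime = hours, u10_ms = u10, sst_c = config$sst_c,
             rain_mmhr = rain$rain_mmhr, wind_dir_deg = dir)
}

# internal: lognormal multiplicative noise factors with E[factor] = 1
lognoise <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  exp(stats::rnorm(n, -s2 / 2, sqrt(s2)))
}

# internal: daily mean of an hourly series
daily_mean <- function(datetime, value) {
  d <- as.Date(datetime, tz = "UTC")
  agg <- tapply(value, d, mean)
  data.frame(date = as.Date(names(agg)), value = as.numeric(agg))
}

#' Simulate daily true water concentrations
#'
#' Coastal sites carry `coupling * flow` (attenuated exponentially with
#' distance from the river mouth) plus a uniform ocean background; the
#' river site carries its median concentration scaled by relative flow.
#' Multiplicative lognormal noise with the configured CV is applied.
#'
#' @param flow data.frame from [simulate_river_flow()].
#' @param sites site table (see [default_sites()]).
#' @param compounds compound registry with `coupling` ((ng/L)/MGD).
#' @param noise_cv coefficient of variation of the lognormal noise.
#' @param seed RNG seed (NULL for no reseeding).
#' @param flow_baseline base flow used to scale the river concentration.
#' @return long data.frame: `site`, `date`, `matrix` = "water",
#'   `compound`, `value`, `unit` = "ng/L".
#' @export
simulate_water_concentrations <- function(flow, sites, compounds,
                                          noise_cv = 0, seed = NULL,
                                          flow_baseline = min(flow$flow_mgd)) {
  daily <- daily_mean(flow$datetime, flow$flow_mgd)
  grid <- expand.grid(site = sites$id, compound = compounds$name,
                      date = daily$date, KEEP.OUT.ATTRS = FALSE,
                      stringsAsFactors = FALSE)
  si <- match(grid$site, sites$id)
  if (anyNA(si)) stop("unknown site id")
  ci <- match(grid$compound, compounds$name)
  fl <- daily$value[match(grid$date, daily$date)]
  atten <- exp(-abs(sites$distance_from_river_km[si]) /
                 sites$gradient_scale[si])
  is_river <- sites$type[si] == "river"
  background <- 0.002 * compounds$river_median_conc[ci]
  truth <- ifelse(
    is_river,
    compounds$river_median_conc[ci] * fl / flow_baseline,
    compounds$coupling[ci] * fl * atten + background
  )
  value <- with_seed(seed, truth * lognoise(length(truth), noise_cv))
  data.frame(site = grid$site, date = grid$date, matrix = "water",
             compound = grid$compound, value = value, unit = "ng/L",
             stringsAsFactors = FALSE)
}

#' Simulate daily true aerosol concentrations
#'
#' A per-site, per-compound airborne pool is propagated daily: wet
#' scavenging removes `exp(-scavenge_rate * wet hours)` during rain,
#' photochemical decay removes `exp(-1/tau_photo)` per day, dry deposition
#' removes `exp(-1/deposition_tau)` per day, and each day adds an SSA
#' increment proportional to that day's mean SSA flux times the water
#' concentration times a compound transfer weight proportional to
#' Kow^gamma. An airborne area-source background is added on top of the
#' pool. Aerosol samples are 23-h integrals assigned to their start day.
#'
#' @param water long water table (true concentrations, ng/L).
#' @param ssa_flux hourly flux series (pg m^-2 day^-1), see
#'   [ssa_flux_series()].
#' @param rain data.frame `datetime`, `rain_mmhr` on the same hourly grid.
#' @param sites,compounds campaign tables.
#' @param scavenge_rate wet-scavenging rate per wet hour.
#' @param deposition_tau_days dry-deposition residence time, days.
#' @param transfer_scale,transfer_gamma transfer-weight model, see
#'   [campaign_config()].
#' @param aerosol_coupling `"sameday"` or `"constant"` (see
#'   [campaign_config()]).
#' @param area_sources logical.
#' @param noise_cv lognormal noise CV.
#' @param seed RNG seed.
#' @return long data.frame: `site`, `date`, `matrix` = "aerosol",
#'   `compound`, `value`, `unit` = "pg/m3".
#' @export
simulate_aerosol_concentrations <- function(water, ssa_flux, rain, sites,
                                            compounds,
                                            scavenge_rate = 0.5,
                                            deposition_tau_days = 2,
                                            transfer_scale = 1e-10,
                                            transfer_gamma = 0.5,
                                            aerosol_coupling = "sameday",
                                            area_sources = TRUE,
                                            noise_cv = 0, seed = NULL) {
  if (!identical(as.numeric(ssa_flux$datetime), as.numeric(rain$datetime))) {
    stop("ssa_flux and rain must share the same hourly time axis")
  }
  flux_daily <- daily_mean(ssa_flux$datetime, ssa_flux$flux)
  wet_hours <- daily_mean(rain$datetime, rain$rain_mmhr > 0)
  wet_hours$value <- wet_hours$value * 24
  days <- flux_daily$date
  aero_sites <- sites$id[sites$type != "river"]
  weight <- transfer_scale * 10^(transfer_gamma * (compounds$log_kow - 2))
  out <- vector("list", length(aero_sites) * nrow(compounds))
  k <- 0
  for (s in aero_sites) {
    for (i in seq_len(nrow(compounds))) {
      w_tab <- water[water$site == s & water$compound == compounds$name[i], ]
      wconc <- w_tab$value[match(days, w_tab$date)]
      if (anyNA(wconc)) stop("water table does not cover the flux days")
      drive <- if (aerosol_coupling == "constant") {
        rep(min(wconc), length(days))
      } else {
        wconc
      }
      pool <- numeric(length(days))
      p <- 0
      loss <- exp(-1 / compounds$tau_photo[i]) *
        exp(-1 / deposition_tau_days)
      for (d in seq_along(days)) {
        p <- p * loss * exp(-scavenge_rate * wet_hours$value[d]) +
          weight[i] * flux_daily$value[d] * drive[d]
        pool[d] <- p
      }
      area <- if (area_sources) compounds$area_source_air[i] else 0
      k <- k + 1
      out[[k]] <- data.frame(site = s, date = days, matrix = "aerosol",
                             compound = compounds$name[i],
                             value = pool + area, unit = "pg/m3",
                             stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  res$value <- with_seed(seed, res$value * lognoise(nrow(res), noise_cv))
  rownames(res) <- NULL
  res
}

#' Derive per-compound/matrix detection limits from generated truth
#'
#' Places the LOD at a quantile of the true concentration distribution so
#' a known fraction of samples censors; LOQ = (10/3) LOD.
#'
#' @param truth long concentration table.
#' @param lod_quantile quantile in `[0, 1)`.
#' @return data.frame `compound`, `matrix`, `lod`, `loq`, `unit`.
#' @export
derive_lods <- function(truth, lod_quantile = 0.05) {
  key <- interaction(truth$compound, truth$matrix, drop = TRUE)
  lod <- tapply(truth$value, key, stats::quantile,
                probs = lod_quantile, names = FALSE)
  parts <- strsplit(names(lod), ".", fixed = TRUE)
  unit <- tapply(truth$unit, key, function(u) u[1])
  data.frame(
    compound = vapply(parts, `[`, "", 1),
    matrix = vapply(parts, `[`, "", 2),
    lod = as.numeric(lod), loq = as.numeric(lod) * 10 / 3,
    unit = as.character(unit), stringsAsFactors = FALSE
  )
}

#' Apply the measurement model: noise and detection-limit censoring
#'
#' Adds multiplicative lognormal measurement noise, then flags values
#' below the LOD as censored at the LOD (the reported value is the LOD,
#' never a smaller point estimate) and values in [LOD, LOQ) as below
#' quantification.
#'
#' @param truth long concentration table (true values).
#' @param lods detection-limit table from [derive_lods()] (or built from
#'   calibration curves via [lod_from_calibration()]).
#' @param measurement_cv lognormal noise CV.
#' @param seed RNG seed.
#' @return the table with noisy `value` and a `censor` column
#'   (`"none"`, `"lt_loq"`, `"lt_lod"`).
#' @export
apply_measurement_model <- function(truth, lods, measurement_cv = 0,
                                    seed = NULL) {
  m <- match(paste(truth$compound, truth$matrix),
             paste(lods$compound, lods$matrix))
  lod <- lods$lod[m]
  loq <- lods$loq[m]
  lod[is.na(lod)] <- 0
  loq[is.na(loq)] <- 0
  value <- with_seed(seed,
                     truth$value * lognoise(nrow(truth), measurement_cv))
  censor <- rep("none", length(value))
  censor[value < loq] <- "lt_loq"
  censor[value < lod] <- "lt_lod"
  value[censor == "lt_lod"] <- lod[censor == "lt_lod"]
  out <- truth
  out$value <- value
  out$censor <- censor
  out
}

#' Simulate a full campaign
#'
#' Runs every generator stage with seeds derived from the configuration
#' seed and returns all intermediate products plus the final measured
#' sample table.
#'
#' @param config a [campaign_config()].
#' @return object of class `campaign`: list with `config`, `rain`, `flow`,
#'   `met`, `ssa_flux` (hourly nearshore surf-zone flux), `water_truth`,
#'   `aerosol_truth`, `lods`, `samples` (long table with `datetime_start`,
#'   `datetime_end`, censor flags).
#' @export
simulate_campaign <- function(config) {
  stopifnot(inherits(config, "campaign_config"))
  rain <- simulate_rain(config)
  flow <- simulate_river_flow(rain, config$flow_baseline, config$flow_gain,
                              config$flow_decay_h)
  met <- simulate_met(config, rain)
  flux <- ssa_flux_series(met, model = "surf_zone", per = "nearshore")
  water <- simulate_water_concentrations(
    flow, config$sites, config$compounds, noise_cv = config$noise_cv,
    seed = stage_seed(config$seed, "water"),
    flow_baseline = config$flow_baseline
  )
  aerosol <- simulate_aerosol_concentrations(
    water, flux, rain, config$sites, config$compounds,
    scavenge_rate = config$scavenge_rate,
    deposition_tau_days = config$deposition_tau_days,
    transfer_scale = config$transfer_scale,
    transfer_gamma = config$transfer_gamma,
    aerosol_coupling = config$aerosol_coupling,
    area_sources = config$area_sources,
    noise_cv = config$noise_cv,
    seed = stage_seed(config$seed, "aerosol")
  )
  truth <- rbind(water, aerosol)
  lods <- derive_lods(truth, config$lod_quantile)
  samples <- apply_measurement_model(truth, lods, config$measurement_cv,
                                     seed = stage_seed(config$seed, "measure"))
  # 23-h aerosol filters start at 00:00 of their assigned day; water grabs
  # are daily instantaneous samples
  start <- as.POSIXct(paste(samples$date, "00:00:00"), tz = "UTC")
  samples$datetime_start <- start
  samples$datetime_end <- start + ifelse(samples$matrix == "aerosol",
                                         23 * 3600, 0)
  structure(list(config = config, rain = rain, flow = flow, met = met,
                 ssa_flux = flux, water_truth = water,
                 aerosol_truth = aerosol, lods = lods, samples = samples),
            class = "campaign")
}

#' @export
print.campaign <- function(x, ...) {
  cat("Synthetic coastal campaign:", x$config$n_days, "days,",
      nrow(x$config$sites), "sites,", nrow(x$config$compounds),
      "compounds,", nrow(x$config$rain_events), "rain events\n")
  cat("  seed", x$config$seed, "| noise_cv", x$config$noise_cv, "\n")
  cat("  samples:", nrow(x$samples), "rows (",
      sum(x$samples$censor == "lt_lod"), "below LOD,",
      sum(x$samples$censor == "lt_loq"), "below LOQ )\n")
  invisible(x)
}

#' Write a campaign to CSV files plus a JSON config
#'
#' Emits `samples.csv` (long format: site, datetime_start, datetime_end,
#' matrix, compound, value, unit, censor), `flow.csv`, `rain.csv`,
#' `wind.csv` (hourly) and `config.json`.
#'
#' @param campaign a [simulate_campaign()] result.
#' @param dir output directory (created if needed).
#' @return invisibly, the vector of file paths written.
#' @export
write_campaign <- function(campaign, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  samples <- campaign$samples[, c("site", "datetime_start", "datetime_end",
                                  "matrix", "compound", "value", "unit",
                                  "censor")]
  utils::write.csv(samples, p("samples.csv"), row.names = FALSE)
  utils::write.csv(campaign$flow, p("flow.csv"), row.names = FALSE)
  utils::write.csv(campaign$rain, p("rain.csv"), row.names = FALSE)
  utils::write.csv(campaign$met, p("wind.csv"), row.names = FALSE)
  cfg <- campaign$config
  cfg$start <- as.character(cfg$start)
  jsonlite::write_json(unclass(cfg), p("config.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(vapply(c("samples.csv", "flow.csv", "rain.csv", "wind.csv",
                     "config.json"), p, ""))
}

#' Read a campaign sample table written by [write_campaign()]
#'
#' @param path path to `samples.csv`.
#' @return long-format data.frame with `date` restored.
#' @export
read_samples <- function(path) {
  x <- utils::read.csv(path, stringsAsFactors = FALSE)
  x$datetime_start <- as.POSIXct(x$datetime_start, tz = "UTC")
  x$datetime_end <- as.POSIXct(x$datetime_end, tz = "UTC")
  x$date <- as.Date(x$datetime_start, tz = "UTC")
  x
}
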