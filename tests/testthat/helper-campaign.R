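# Shared fixtures, all generated in code.

# default study-condition campaign
study_campaign <- function(seed = 1, ...) {
  simulate_campaign(campaign_config(seed = seed, ...))
}

# Analytic noiseless fixture: four equal-duration events with distinct
# intensities; wind is a step function holding a per-event value from the
# first wet hour through the end of the accumulation window, so the
# post-event aerosol increase is exactly linear in the integrated SSA flux
# (constant-water coupling, no losses).
analytic_campaign <- function() {
  ev <- data.frame(start_day = c(6, 16, 26, 36), duration_h = 24,
                   intensity_mm_h = c(2, 5, 9, 12))
  cfg <- campaign_config(n_days = 46, rain_events = ev, noise_cv = 0,
                         measurement_cv = 0, scavenge_rate = 0,
                         deposition_tau_days = Inf,
                         aerosol_coupling = "constant", lod_quantile = 0)
  rain <- simulate_rain(cfg)
  flow <- simulate_river_flow(rain, cfg$flow_baseline, cfg$flow_gain,
                              cfg$flow_decay_h)
  day <- as.numeric(as.Date(rain$datetime, tz = "UTC") - cfg$start) + 1
  u <- rep(3, nrow(rain))
  for (i in seq_len(nrow(ev))) {
    hit <- day >= ev$start_day[i] & day < ev$start_day[i] + 5
    u[hit] <- 3 + ev$intensity_mm_h[i]
  }
  met <- data.frame(datetime = rain$datetime, u10_ms = u, sst_c = 16,
                    rain_mmhr = rain$rain_mmhr, wind_dir_deg = 270)
  flux <- ssa_flux_series(met, "surf_zone", per = "nearshore")
  water <- simulate_water_concentrations(flow, cfg$sites, cfg$compounds,
                                         noise_cv = 0, seed = NULL,
                                         flow_baseline = cfg$flow_baseline)
  aero <- simulate_aerosol_concentrations(
    water, flux, rain, cfg$sites, cfg$compounds, scavenge_rate = 0,
    deposition_tau_days = Inf, aerosol_coupling = "constant", noise_cv = 0
  )
  structure(list(config = cfg, rain = rain, flow = flow, met = met,
                 ssa_flux = flux, water_truth = water,
                 aerosol_truth = aero, lods = NULL, samples = NULL),
            class = "campaign")
}

# lognormal "truth" draws for the censoring Monte-Carlo
with_seed_values <- function(seed, n) {
  set.seed(seed)
  stats::rlnorm(n, log(50), 0.8)
}

# throwaway directory cleaned up with the test frame
withr_local_tempdir <- function(env = parent.frame()) {
  dir <- tempfile("coastspray-")
  dir.create(dir)
  withr::defer(unlink(dir, recursive = TRUE), envir = env)
  dir
}

# brute-force two-sided Mann-Whitney permutation p-value by full
# enumeration of group assignments (independent oracle for site_compare)
mw_enumerate_p <- function(a, b) {
  n1 <- length(a)
  pool <- c(a, b)
  r <- rank(pool)
  u_of <- function(idx) sum(r[idx]) - n1 * (n1 + 1) / 2
  mu <- n1 * length(b) / 2
  obs <- abs(u_of(seq_len(n1)) - mu)
  sets <- utils::combn(length(pool), n1)
  dev <- abs(apply(sets, 2, u_of) - mu)
  mean(dev >= obs - 1e-9)
}
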