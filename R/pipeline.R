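#' End-to-end campaign analyses
#'
#' Wrappers that chain event detection, window deltas and regressions into
#' the two headline event analyses (water-vs-flow and
#' aerosol-vs-integrated-SSA-flux) and the AF-Kow recovery, as run on a
#' generated or imported campaign.
#'
#' @name pipeline
NULL

# internal: daily mean river flow as a date/value series
daily_flow_series <- function(flow) {
  d <- daily_mean(flow$datetime, flow$flow_mgd)
  names(d) <- c("date", "value")
  d
}

#' Event regression of water concentration change on flow change
#'
#' For each detected rain event, computes the change in daily water
#' concentration at a site (wet window minus dry pre-window) and the
#' matching change in river flow, then regresses the concentration deltas
#' on the flow deltas (free intercept).
#'
#' @param campaign a [simulate_campaign()] result (or a list with `rain`,
#'   `flow`, `samples`).
#' @param site water site id (default "IB").
#' @param compound compound name (default the sewage tracer).
#' @param use_truth regress the noise-free truth table instead of the
#'   measured samples.
#' @return list with `events` (per-event deltas) and `fit`
#'   (`spray_regression`).
#' @export
analyze_water_flow <- function(campaign, site = "IB",
                               compound = "benzoylecgonine",
                               use_truth = FALSE) {
  events <- detect_events(campaign$rain)
  if (nrow(events) == 0) stop("no rain events detected")
  tab <- if (use_truth) campaign$water_truth else campaign$samples
  ser <- daily_series(tab, site, compound, "water")
  fl <- daily_flow_series(campaign$flow)
  rows <- lapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    dw <- event_deltas(ev, ser, post = "wet")
    df <- event_deltas(ev, fl, post = "wet")
    data.frame(event_id = ev$event_id, delta_conc = dw$delta,
               sd_conc = dw$sd, delta_flow = df$delta, sd_flow = df$sd)
  })
  deltas <- do.call(rbind, rows)
  list(events = deltas,
       fit = regress(deltas$delta_flow, deltas$delta_conc))
}

#' Event regression of aerosol accumulation on integrated SSA flux
#'
#' For each rain event with aerosol coverage in its post-rain window,
#' computes the aerosol concentration change (accumulation window minus
#' pre-window) and the SSA mass flux integrated over the accumulation
#' window, then regresses the aerosol deltas on the integrated fluxes.
#' Events without any post-window aerosol sample are dropped and reported.
#'
#' @param campaign a [simulate_campaign()] result.
#' @param site aerosol site id (default "IB").
#' @param compound compound name.
#' @param use_truth regress the noise-free truth table.
#' @return list with `events`, `dropped_events` and `fit`.
#' @export
analyze_aerosol_flux <- function(campaign, site = "IB",
                                 compound = "benzoylecgonine",
                                 use_truth = FALSE) {
  events <- detect_events(campaign$rain)
  if (nrow(events) == 0) stop("no rain events detected")
  tab <- if (use_truth) campaign$aerosol_truth else campaign$samples
  ser <- daily_series(tab, site, compound, "aerosol")
  covered <- vapply(seq_len(nrow(events)), function(i) {
    any(ser$date %in% event_window_dates(events[i, ], "accumulation"))
  }, logical(1))
  dropped <- events$event_id[!covered]
  events <- events[covered, ]
  if (nrow(events) < 2) stop("fewer than 2 events with aerosol coverage")
  rows <- lapply(seq_len(nrow(events)), function(i) {
    ev <- events[i, ]
    da <- event_deltas(ev, ser, post = "accumulation")
    sum_flux <- integrate_flux(campaign$ssa_flux,
                               c(ev$wet_end, ev$accum_end))
    data.frame(event_id = ev$event_id, delta_aerosol = da$delta,
               sd_aerosol = da$sd, sum_flux = sum_flux)
  })
  deltas <- do.call(rbind, rows)
  list(events = deltas, dropped_events = dropped,
       fit = regress(deltas$sum_flux, deltas$delta_aerosol))
}

#' AF-Kow analysis of a campaign
#'
#' Computes per-pair aerosolization factors, summarizes them per compound
#' and fits the log AF vs log Kow regression (excluding surface-only
#' compounds).
#'
#' @param campaign a [simulate_campaign()] result.
#' @param sites site ids to pool.
#' @param policy censoring policy, see [aerosolization_factor()].
#' @return list with `pairs`, `summary` and `fit` (with `slope_se`).
#' @export
analyze_af_kow <- function(campaign, sites = c("BF", "IB", "SS"),
                           policy = "exclude") {
  af <- aerosolization_factor(campaign$samples, sites = sites,
                              policy = policy)
  summ <- summarize_enrichment(af, campaign$config$compounds)
  list(pairs = af$pairs, excluded = af$excluded, summary = summ,
       fit = regress_logaf_logkow(summ))
}

#' Compartmental flux chain for one compound from campaign data
#'
#' Builds the river-to-ocean, ocean-to-air, onshore and inhalation
#' estimates from the campaign's sample table using median and maximum
#' uncensored concentrations.
#'
#' @param campaign a [simulate_campaign()] result.
#' @param compound compound name.
#' @param water_site ocean-water site for the ocean-to-air step.
#' @param air_site aerosol site for onshore transfer and inhalation.
#' @param params a [transfer_params()].
#' @return data.frame of flux estimates (one row per boundary) plus an
#'   `inhalation_ng_h` attribute with the median/max exposures.
#' @export
compartment_fluxes <- function(campaign, compound,
                               water_site = "IB", air_site = "IB",
                               params = transfer_params()) {
  s <- campaign$samples
  pick <- function(site, matrix) {
    x <- s[s$site == site & s$matrix == matrix & s$compound == compound &
             s$censor != "lt_lod", "value"]
    if (length(x) == 0) stop("no uncensored ", matrix, " values at ", site)
    x
  }
  river <- pick("TJR", "water")
  ocean <- pick(water_site, "water")
  air_pg <- pick(air_site, "aerosol")           # pg/m3
  air <- convert_conc(air_pg, "pg/m3", "ng/m3")
  flow_med <- stats::median(daily_flow_series(campaign$flow)$value)
  ssa_med <- stats::median(campaign$ssa_flux$flux)
  out <- rbind(
    river_to_ocean(compound, stats::median(river), max(river), flow_med),
    ocean_to_air(compound, stats::median(ocean), max(ocean), ssa_med,
                 params),
    onshore_transfer(compound, stats::median(air), max(air), params)
  )
  per_km <- out[out$boundary == "onshore", c("median_rate", "max_rate")] /
    (params$coastline_length_m / 1000)
  out <- rbind(out, global_extrapolation(compound, per_km$median_rate,
                                         per_km$max_rate, params))
  attr(out, "inhalation_ng_h") <- c(
    median = inhalation(stats::median(air), params$inhalation_rate_m3_h),
    max = inhalation(max(air), params$inhalation_rate_m3_h)
  )
  out
}
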