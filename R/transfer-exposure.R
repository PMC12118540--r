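#' Compartmental mass-transfer and inhalation-exposure estimators
#'
#' Order-of-magnitude estimators for the chain river -> ocean -> air ->
#' inhalation: river discharge of a pollutant (concentration x flow),
#' its enrichment-scaled contribution to the sea spray aerosol mass flux,
#' the onshore transfer through a well-mixed marine boundary layer, the
#' inhalation dose, and a global coastline extrapolation. Every operation
#' is linear (degree-1 homogeneous) in its concentration argument, and
#' median/max inputs propagate to median/max outputs.
#'
#' @name transfer_exposure
NULL

#' Transfer model parameters
#'
#' Defaults are the model's stated constants: a 200 m well-mixed marine
#' boundary layer, a steady 5 m/s onshore breeze, a 1 km coastline
#' segment, a low-intensity inhalation rate of 0.7 m3/h, and the global
#' extrapolation assumptions that half the world's coastline is heavily
#' affected and wind blows onshore half the time. The sea spray
#' enrichment factor and the global coastline length come from the
#' constants registry (assumption-flagged) and can be overridden.
#'
#' @param enrichment_factor sodium-normalized sea spray enrichment factor
#'   (dimensionless).
#' @param seawater_na_g_l seawater sodium reference concentration, g/L.
#' @param boundary_layer_height_m marine boundary layer height, m.
#' @param onshore_wind_ms onshore wind speed, m/s.
#' @param coastline_length_m coastline segment length, m.
#' @param inhalation_rate_m3_h inhalation rate, m3/h.
#' @param global_coastline_km global coastline length, km.
#' @param coast_impacted_fraction fraction of coastline heavily affected.
#' @param onshore_time_fraction fraction of time with onshore wind.
#' @return object of class `transfer_params`.
#' @export
transfer_params <- function(enrichment_factor = ssa_const("enrichment_factor"),
                            seawater_na_g_l = ssa_const("seawater_na"),
                            boundary_layer_height_m = 200,
                            onshore_wind_ms = 5,
                            coastline_length_m = 1000,
                            inhalation_rate_m3_h = 0.7,
                            global_coastline_km = ssa_const("global_coastline_km"),
                            coast_impacted_fraction = 0.5,
                            onshore_time_fraction = 0.5) {
  p <- list(enrichment_factor = enrichment_factor,
            seawater_na_g_l = seawater_na_g_l,
            boundary_layer_height_m = boundary_layer_height_m,
            onshore_wind_ms = onshore_wind_ms,
            coastline_length_m = coastline_length_m,
            inhalation_rate_m3_h = inhalation_rate_m3_h,
            global_coastline_km = global_coastline_km,
            coast_impacted_fraction = coast_impacted_fraction,
            onshore_time_fraction = onshore_time_fraction)
  pos <- p[setdiff(names(p), "enrichment_factor")]
  if (any(!vapply(pos, function(x) is.numeric(x) && x > 0, TRUE))) {
    stop("all transfer parameters must be positive numbers")
  }
  if (!is.numeric(p$enrichment_factor) || p$enrichment_factor < 0) {
    stop("enrichment_factor must be a non-negative number")
  }
  structure(p, class = "transfer_params")
}

# internal: assemble a flux estimate row
flux_estimate <- function(compound, boundary, median_rate, max_rate, units,
                          exploratory = FALSE) {
  if (any(max_rate < median_rate, na.rm = TRUE)) {
    stop("max_rate must be >= median_rate")
  }
  data.frame(compound = compound, boundary = boundary,
             median_rate = median_rate, max_rate = max_rate, units = units,
             exploratory = exploratory, stringsAsFactors = FALSE)
}

#' River-to-ocean pollutant discharge
#'
#' Daily discharge = concentration x flow, with 1 US gallon = 3.78541 L,
#' so 1 ug/L at 1 MGD is 3.78541 g/day.
#'
#' @param compound compound label.
#' @param conc_median_ng_l,conc_max_ng_l median and maximum river
#'   concentrations, ng/L (>= 0).
#' @param flow_mgd river flow, MGD (> 0).
#' @return one-row data.frame (`boundary = "river_to_ocean"`), rates in
#'   g/day.
#' @export
river_to_ocean <- function(compound, conc_median_ng_l, conc_max_ng_l,
                           flow_mgd) {
  if (conc_median_ng_l < 0 || conc_max_ng_l < 0 || flow_mgd <= 0) {
    stop("concentrations must be >= 0 and flow > 0")
  }
  l_day <- mgd_to_l_day(flow_mgd)
  flux_estimate(compound, "river_to_ocean",
                conc_median_ng_l * 1e-9 * l_day,
                conc_max_ng_l * 1e-9 * l_day, "g/day")
}

#' Ocean-to-air pollutant flux in sea spray
#'
#' Pollutant flux = SSA mass flux x enrichment factor x (water
#' concentration / seawater sodium reference). Tagged exploratory because
#' field enrichment factors for these compounds are not measured.
#'
#' @param compound compound label.
#' @param water_median_ng_l,water_max_ng_l uncensored ocean-water
#'   concentrations, ng/L.
#' @param ssa_mass_flux_pg_m2_day SSA mass flux, pg m^-2 day^-1.
#' @param params a [transfer_params()].
#' @param censored logical; when TRUE the estimate is suppressed (NA).
#' @return one-row data.frame (`boundary = "ocean_to_air"`), rates in
#'   pg m^-2 day^-1, `exploratory = TRUE`.
#' @export
ocean_to_air <- function(compound, water_median_ng_l, water_max_ng_l,
                         ssa_mass_flux_pg_m2_day,
                         params = transfer_params(), censored = FALSE) {
  if (censored) {
    return(flux_estimate(compound, "ocean_to_air", NA_real_, NA_real_,
                         "pg/m2/day", exploratory = TRUE))
  }
  ratio <- function(wc) (wc * 1e-9) / params$seawater_na_g_l # g/L over g/L
  flux_estimate(compound, "ocean_to_air",
                ssa_mass_flux_pg_m2_day * params$enrichment_factor *
                  ratio(water_median_ng_l),
                ssa_mass_flux_pg_m2_day * params$enrichment_factor *
                  ratio(water_max_ng_l),
                "pg/m2/day", exploratory = TRUE)
}

#' Onshore mass transfer through the marine boundary layer
#'
#' rate = air concentration x wind speed x 86400 s/day x boundary layer
#' height x coastline length; 1 ng/m3 with the default parameters gives
#' 86.4 g/day over a 1 km segment.
#'
#' @param compound compound label.
#' @param air_median_ng_m3,air_max_ng_m3 air concentrations, ng/m3 (>= 0).
#' @param params a [transfer_params()].
#' @return one-row data.frame (`boundary = "onshore"`), rates in g/day per
#'   coastline segment.
#' @export
onshore_transfer <- function(compound, air_median_ng_m3, air_max_ng_m3,
                             params = transfer_params()) {
  if (air_median_ng_m3 < 0 || air_max_ng_m3 < 0) {
    stop("air concentrations must be non-negative")
  }
  k <- params$onshore_wind_ms * 86400 * params$boundary_layer_height_m *
    params$coastline_length_m * 1e-9 # m3/day x g/ng
  flux_estimate(compound, "onshore", air_median_ng_m3 * k,
                air_max_ng_m3 * k, "g/day")
}

#' Inhalation exposure
#'
#' exposure = air concentration x inhalation rate.
#'
#' @param air_conc_ng_m3 air concentration, ng/m3 (>= 0, vectorized).
#' @param rate_m3_h inhalation rate, m3/h (> 0).
#' @return exposure, ng/h.
#' @export
inhalation <- function(air_conc_ng_m3, rate_m3_h = 0.7) {
  if (any(air_conc_ng_m3 < 0)) stop("air concentration must be >= 0")
  if (rate_m3_h <= 0) stop("inhalation rate must be positive")
  air_conc_ng_m3 * rate_m3_h
}

#' Global annual extrapolation of a per-kilometre onshore transfer rate
#'
#' annual mass = per-km daily rate x global coastline length x impacted
#' fraction x onshore-time fraction x 365.25 days. Flagged exploratory.
#'
#' @param compound compound label.
#' @param median_g_day_km,max_g_day_km onshore transfer rates, g/day/km.
#' @param params a [transfer_params()]; `global_coastline_km` must be set.
#' @return one-row data.frame (`boundary = "global"`), rates in g/year,
#'   `exploratory = TRUE`.
#' @export
global_extrapolation <- function(compound, median_g_day_km, max_g_day_km,
                                 params = transfer_params()) {
  if (median_g_day_km < 0 || max_g_day_km < 0) {
    stop("rates must be non-negative")
  }
  if (is.null(params$global_coastline_km) ||
      !is.finite(params$global_coastline_km)) {
    stop("global coastline constant missing")
  }
  k <- params$global_coastline_km * params$coast_impacted_fraction *
    params$onshore_time_fraction * 365.25
  flux_estimate(compound, "global", median_g_day_km * k,
                max_g_day_km * k, "g/year", exploratory = TRUE)
}

#' Photochemical correction factor for aged aerosol concentrations
#'
#' A compound with first-order photochemical e-folding lifetime tau,
#' measured `elapsed` days after emission, is depleted by exp(-elapsed /
#' tau); the correction factor to recover the freshly emitted
#' concentration is exp(elapsed / tau) >= 1. With a 4-day lifetime and a
#' 3-4 day accumulation period the factor is ~2.1-2.7, i.e. measured
#' concentrations are two to three times lower than freshly emitted ones.
#'
#' @param tau_days e-folding lifetime, days (> 0; Inf for photostable).
#' @param elapsed_days aging time, days (>= 0).
#' @return decay correction factor >= 1 (vectorized).
#' @export
photochemical_factor <- function(tau_days, elapsed_days) {
  if (any(tau_days <= 0)) stop("tau must be positive")
  if (any(elapsed_days < 0)) stop("elapsed time must be non-negative")
  exp(elapsed_days / tau_days)
}
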