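#' Sea spray aerosol mass-flux parameterizations
#'
#' Two SSA source functions are provided. The surf-zone model has an
#' exponential wind dependence and a power-law size distribution and is
#' appropriate for the enhanced production in the nearshore wave-breaking
#' band; the open-ocean model combines a whitecap-fraction wind scaling
#' (u10^3.41) with a cubic sea-surface-temperature factor. Both are
#' integrated over the same physical particle size range and returned as a
#' dry mass flux in the package's canonical unit, pg m^-2 day^-1.
#'
#' @name source_functions
NULL

# internal: dry mass (pg) of a sea salt particle with radius r80 (um) at
# 80% RH; r_dry = r80/2, volume in m3, density kg m-3, 1 kg = 1e15 pg
.dry_mass_pg <- function(r80_um, reg = ssa_constants()) {
  r_dry_m <- r80_um * ssa_const("r80_to_dry", reg) * 1e-6
  ssa_const("dry_density", reg) * (4 / 3) * pi * r_dry_m^3 * 1e15
}

# internal: size-integrated mass factor for the surf-zone model at u10 = 0,
# in pg m-2 s-1; closed-form integral of a * D^c * m(D) dD over the D80
# validity range (m(D) is cubic in D so the integrand is a pure power law)
.surf_base_mass_flux <- function(reg = ssa_constants()) {
  a <- ssa_const("surf_coef", reg)
  cc <- ssa_const("surf_size_exp", reg)
  rng <- ssa_const("surf_d80_range", reg)
  # m(D80) = dry_mass_pg(D80/2) = k * D80^3
  k <- .dry_mass_pg(0.5, reg) # mass at r80 = 0.5 um i.e. D80 = 1 um
  p <- cc + 3
  a * k * (rng[2]^(p + 1) - rng[1]^(p + 1)) / (p + 1)
}

#' Surf-zone SSA mass flux
#'
#' Exponential-wind surf-zone source function integrated to a dry mass
#' flux. By default the flux is per square metre of surf zone; with
#' `per = "nearshore"` the production of a surf strip of registry width is
#' averaged over the marine boundary-layer footprint so it is directly
#' comparable with the open-ocean model.
#'
#' @param u10 wind speed at 10 m, m/s (vectorized; must be >= 0).
#' @param per `"surf_zone"` (default) or `"nearshore"`.
#' @param registry constants registry, see [ssa_constants()].
#' @return data.frame with columns `u10`, `flux` (pg m^-2 day^-1) and
#'   `model` (`"surf_zone"`).
#' @export
ssa_flux_surfzone <- function(u10, per = c("surf_zone", "nearshore"),
                              registry = ssa_constants()) {
  per <- match.arg(per)
  if (any(!is.finite(u10)) || any(u10 < 0)) {
    stop("u10 must be finite and non-negative")
  }
  b <- ssa_const("surf_wind_coef", registry)
  flux <- .surf_base_mass_flux(registry) * exp(b * u10) * 86400
  if (per == "nearshore") {
    flux <- flux * ssa_const("surf_zone_width", registry) /
      ssa_const("footprint_width", registry)
  }
  data.frame(u10 = u10, flux = flux, model = "surf_zone",
             stringsAsFactors = FALSE)
}

# internal: Gong (2003) number flux density dF/dr80 at u10 = 1 m/s,
# m-2 s-1 um-1 (the wind speed enters only through u10^3.41)
.gong_shape <- function(r80, theta = 30) {
  A <- 4.7 * (1 + theta * r80)^(-0.017 * r80^(-1.44))
  B <- (0.433 - log10(r80)) / 0.433
  1.373 * r80^(-A) * (1 + 0.057 * r80^3.45) * 10^(1.607 * exp(-B^2))
}

# internal: size-integrated open-ocean mass factor at u10 = 1 m/s, SST
# factor 1, pg m-2 s-1 (2000-point trapezoid over the matched size range)
.gong_base_mass_flux <- function(reg = ssa_constants()) {
  rng <- ssa_const("gong_r80_range", reg)
  r <- seq(rng[1], rng[2], length.out = 2000)
  y <- .gong_shape(r, ssa_const("gong_theta", reg)) * .dry_mass_pg(r, reg)
  sum((y[-1] + y[-length(y)]) / 2 * diff(r))
}

#' Open-ocean wind/SST SSA mass flux
#'
#' Whitecap-scaled size distribution with a cubic sea-surface-temperature
#' factor, integrated to a dry mass flux per square metre of ocean.
#' Temperatures outside the parameterization's fitted range are clamped
#' with a warning and flagged.
#'
#' @param u10 wind speed at 10 m, m/s (vectorized; must be >= 0).
#' @param sst sea surface temperature, degrees C (scalar or same length).
#' @param registry constants registry.
#' @return data.frame with columns `u10`, `sst`, `flux` (pg m^-2 day^-1),
#'   `model` (`"wind_sst"`) and logical `clamped`.
#' @export
ssa_flux_wind_sst <- function(u10, sst, registry = ssa_constants()) {
  if (any(!is.finite(u10)) || any(u10 < 0)) {
    stop("u10 must be finite and non-negative")
  }
  n <- max(length(u10), length(sst))
  u10 <- rep_len(u10, n)
  sst <- rep_len(sst, n)
  rng <- ssa_const("sst_valid_range", registry)
  clamped <- sst < rng[1] | sst > rng[2]
  if (any(clamped)) {
    warning("SST outside validity range [", rng[1], ", ", rng[2],
            "] degC; clamped")
    sst <- pmin(pmax(sst, rng[1]), rng[2])
  }
  p <- ssa_const("sst_poly", registry)
  sst_fac <- p[1] + p[2] * sst + p[3] * sst^2 + p[4] * sst^3
  flux <- .gong_base_mass_flux(registry) *
    u10^ssa_const("gong_wind_exp", registry) * sst_fac * 86400
  data.frame(u10 = u10, sst = sst, flux = flux, model = "wind_sst",
             clamped = clamped, stringsAsFactors = FALSE)
}

#' Hourly SSA flux series from a meteorological series
#'
#' @param met data.frame with columns `datetime` (POSIXct, hourly) and
#'   `u10_ms`; `sst_c` is required for the wind/SST model.
#' @param model `"surf_zone"` or `"wind_sst"`.
#' @param per areal convention for the surf-zone model, see
#'   [ssa_flux_surfzone()].
#' @param registry constants registry.
#' @return data.frame `datetime`, `flux` (pg m^-2 day^-1), `model`.
#' @export
ssa_flux_series <- function(met, model = c("surf_zone", "wind_sst"),
                            per = "nearshore", registry = ssa_constants()) {
  model <- match.arg(model)
  stopifnot(all(c("datetime", "u10_ms") %in% names(met)))
  flux <- if (model == "surf_zone") {
    ssa_flux_surfzone(met$u10_ms, per = per, registry = registry)$flux
  } else {
    if (!"sst_c" %in% names(met)) stop("wind_sst model requires met$sst_c")
    ssa_flux_wind_sst(met$u10_ms, met$sst_c, registry = registry)$flux
  }
  data.frame(datetime = met$datetime, flux = flux, model = model,
             stringsAsFactors = FALSE)
}

#' Integrate an SSA flux series over a time window
#'
#' Trapezoidal integration on the hourly grid, with linear interpolation at
#' the window endpoints so integrals are exactly additive over adjacent
#' windows. Flux is pg m^-2 day^-1 and time is measured in days, so the
#' result is a mass per area in pg m^-2.
#'
#' @param series data.frame with `datetime` (POSIXct) and `flux`.
#' @param window length-2 POSIXct (or numeric days) `c(t0, t1)` within the
#'   series span; `t1 < t0` is an error, `t1 == t0` integrates to zero.
#' @return integrated flux, pg m^-2.
#' @export
integrate_flux <- function(series, window) {
  stopifnot(all(c("datetime", "flux") %in% names(series)))
  as_days <- function(x) {
    if (inherits(x, "POSIXt") || inherits(x, "Date")) {
      as.numeric(as.POSIXct(x)) / 86400
    } else {
      as.numeric(x) # already days
    }
  }
  t <- as_days(series$datetime)
  w <- as_days(window)
  if (length(w) != 2 || any(!is.finite(w))) stop("window must be c(t0, t1)")
  if (w[2] < w[1]) stop("window end precedes start")
  if (w[1] < min(t) || w[2] > max(t)) stop("window outside series span")
  if (w[2] == w[1]) return(0)
  keep <- t > w[1] & t < w[2]
  f0 <- stats::approx(t, series$flux, xout = w)$y
  tt <- c(w[1], t[keep], w[2])
  ff <- c(f0[1], series$flux[keep], f0[2])
  sum((ff[-1] + ff[-length(ff)]) / 2 * diff(tt))
}
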