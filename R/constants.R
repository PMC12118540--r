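#' Constants registry for sea spray aerosol source functions and transfer
#' models
#'
#' All externally sourced numerics used by the flux and transfer models are
#' collected here with their citation (or an explicit assumption flag) so
#' they can be audited and overridden in one place, rather than being
#' hard-coded inline.
#'
#' @return a named list; each entry is a list with `value`, `units`,
#'   `source` and logical `assumption`.
#' @export
ssa_constants <- function() {
  reg <- function(value, units, source, assumption = FALSE) {
    list(value = value, units = units, source = source,
         assumption = assumption)
  }
  list(
    # surf-zone source function: dF/dD80 = a * exp(b * u10) * D80^c,
    # number flux per m2 of surf zone per second per micrometre,
    # D80 = particle diameter at 80% relative humidity
    surf_coef       = reg(1.1e5, "m-2 s-1 um-1",
                          "de Leeuw et al. (2000) J. Geophys. Res. 105, 29397"),
    surf_wind_coef  = reg(0.23, "per (m/s)",
                          "de Leeuw et al. (2000), exponential wind dependence"),
    surf_size_exp   = reg(-1.65, "dimensionless",
                          "de Leeuw et al. (2000), power-law size dependence"),
    surf_d80_range  = reg(c(1.6, 20), "um diameter at 80% RH",
                          "de Leeuw et al. (2000), validity range"),
    surf_u10_range  = reg(c(0, 9), "m/s",
                          "de Leeuw et al. (2000), wind validity range"),

    # open-ocean wind/SST source function: Gong (2003) size distribution
    # (whitecap scaling u10^3.41) with the Jaegle et al. (2011) cubic
    # sea-surface-temperature factor
    gong_theta      = reg(30, "dimensionless",
                          "Gong (2003) Global Biogeochem. Cycles 17, 1097"),
    gong_wind_exp   = reg(3.41, "dimensionless",
                          "Monahan et al. (1986) whitecap scaling, via Gong (2003)"),
    sst_poly        = reg(c(0.3, 0.1, -0.0076, 0.00021), "per degC powers 0..3",
                          "Jaegle et al. (2011) Atmos. Chem. Phys. 11, 3137"),
    sst_valid_range = reg(c(0, 30), "degC",
                          "Jaegle et al. (2011), fitted SST range"),
    gong_r80_range  = reg(c(0.8, 10), "um radius at 80% RH",
                          "matched to the surf-zone D80 range (r80 = D80/2)"),

    # microphysics used to convert number flux to dry mass flux
    dry_density     = reg(2160, "kg m-3", "sea salt (NaCl) dry density"),
    r80_to_dry      = reg(0.5, "dimensionless",
                          "r_dry ~ r80 / 2 for sea salt (Lewis & Schwartz 2004)"),

    # areal conventions for comparing the two models on a common footprint
    surf_zone_width = reg(50, "m",
                          "typical S. California surf-zone width",
                          assumption = TRUE),
    footprint_width = reg(54000, "m",
                          "marine boundary-layer fetch: 5 m/s onshore breeze x 3 h sea-breeze residence",
                          assumption = TRUE),

    # transfer model constants
    seawater_na     = reg(10.8, "g/L", "standard seawater sodium concentration"),
    enrichment_factor = reg(100, "dimensionless",
                          "order of magnitude of sea spray enrichment factors measured for PFAS (Johansson et al. 2019)",
                          assumption = TRUE),
    global_coastline_km = reg(1.634e6, "km",
                          "high-resolution global shoreline length (OpenStreetMap-derived)",
                          assumption = TRUE)
  )
}

# internal: fetch a registry value
ssa_const <- function(name, registry = ssa_constants()) {
  entry <- registry[[name]]
  if (is.null(entry)) stop("unknown registry constant: ", name)
  entry$value
}
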