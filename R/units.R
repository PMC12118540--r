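#' Unit conversion helpers
#'
#' Concentrations carry explicit unit strings throughout the package; mixing
#' water-phase units (per litre) with air-phase units (per cubic metre)
#' without an explicit matrix-aware conversion is a hard error.
#'
#' @name units
NULL

# grams per unit, keyed by concentration unit string; the denominator
# dimension is tracked separately so water and air units never silently mix
.conc_units <- data.frame(
  unit  = c("ng/L", "pg/L", "ug/L", "g/L", "ng/m3", "pg/m3", "ug/m3", "g/m3"),
  gram  = c(1e-9, 1e-12, 1e-6, 1, 1e-9, 1e-12, 1e-6, 1),
  basis = c("L", "L", "L", "L", "m3", "m3", "m3", "m3"),
  stringsAsFactors = FALSE
)

#' Convert a concentration between units of the same matrix basis
#'
#' @param value numeric vector of concentrations.
#' @param from,to unit strings, one of `"ng/L"`, `"pg/L"`, `"ug/L"`, `"g/L"`
#'   (water) or `"ng/m3"`, `"pg/m3"`, `"ug/m3"`, `"g/m3"` (air).
#' @return numeric vector in the `to` unit.
#' @examples
#' convert_conc(5, "ng/L", "pg/L")   # 5000
#' @export
convert_conc <- function(value, from, to) {
  i <- match(from, .conc_units$unit)
  j <- match(to, .conc_units$unit)
  if (is.na(i) || is.na(j)) {
    stop("unknown concentration unit: ", if (is.na(i)) from else to)
  }
  if (.conc_units$basis[i] != .conc_units$basis[j]) {
    stop("refusing to convert between per-", .conc_units$basis[i],
         " and per-", .conc_units$basis[j],
         " units without a matrix volume; convert explicitly")
  }
  value * .conc_units$gram[i] / .conc_units$gram[j]
}

#' Litres per million US gallons (exact, 1 gal = 3.78541 L)
#' @export
L_PER_MGAL <- 3.78541e6

#' Convert river flow from MGD to litres per day
#' @param mgd flow in millions of US gallons per day.
#' @return litres per day.
#' @export
mgd_to_l_day <- function(mgd) mgd * L_PER_MGAL

# internal: run code under a temporary RNG state so generators are
# deterministic without clobbering the caller's stream
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed %% 2147483647L))
  }
  force(code)
}

# internal: derive a per-stage seed below 2^31 from a campaign seed
stage_seed <- function(seed, stage) {
  offs <- c(flow = 101L, wind = 211L, water = 307L, aerosol = 401L,
            measure = 503L)
  (as.integer(seed) %% 2000000000L) + offs[[stage]]
}
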