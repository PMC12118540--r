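#' External calibration, detection limits and blank-based QA/QC
#'
#' Quantification follows the external-calibration convention in which
#' extraction recoveries are folded into the calibrated response factors:
#' an ordinary least-squares line with free intercept is fit to instrument
#' response versus spiked mass, and the limit of detection is defined as
#' three times the standard error of the y intercept divided by the
#' sensitivity. The limit of quantification uses the conventional 3-sigma /
#' 10-sigma pairing, LOQ = (10/3) LOD.
#'
#' @name quant_qc
NULL

#' Default calibration levels (ng per sample)
#'
#' Three-point external standard levels spanning two orders of magnitude.
#' @export
CALIBRATION_LEVELS_NG <- c(1.37, 13.7, 137)

#' Fit an external calibration curve
#'
#' @param levels spiked masses, ng per sample (>= 3 distinct values).
#' @param responses instrument responses (arbitrary units), same length.
#' @return an object of class `calibration_curve`: list with `sensitivity`
#'   (response per ng), `intercept`, `intercept_se`, `lod`, `loq` (ng per
#'   sample), `n`, and the fitted `lm` in `$fit`.
#' @examples
#' fit_calibration(c(1.37, 13.7, 137), 2 * c(1.37, 13.7, 137))
#' @export
fit_calibration <- function(levels, responses) {
  if (length(levels) != length(responses)) {
    stop("levels and responses must have the same length")
  }
  if (length(unique(levels)) < 3) {
    stop("invalid calibration curve: fewer than 3 distinct levels")
  }
  if (length(unique(responses)) == 1) {
    stop("invalid calibration curve: all responses equal")
  }
  fit <- stats::lm(responses ~ levels)
  co <- summary(fit)$coefficients
  sens <- co["levels", "Estimate"]
  if (!is.finite(sens) || sens <= 0) {
    stop("invalid calibration curve: non-positive sensitivity")
  }
  int_se <- co["(Intercept)", "Std. Error"]
  if (!is.finite(int_se)) int_se <- 0 # exact fit
  lod <- 3 * int_se / sens
  structure(list(
    levels = levels, responses = responses,
    sensitivity = sens,
    intercept = co["(Intercept)", "Estimate"],
    intercept_se = int_se,
    lod = lod, loq = (10 / 3) * lod,
    n = length(levels), fit = fit
  ), class = "calibration_curve")
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat("External calibration curve (", x$n, " points)\n", sep = "")
  cat(sprintf("  sensitivity : %.4g response/ng\n", x$sensitivity))
  cat(sprintf("  intercept   : %.4g (SE %.4g)\n", x$intercept, x$intercept_se))
  cat(sprintf("  LOD / LOQ   : %.4g / %.4g ng per sample\n", x$lod, x$loq))
  invisible(x)
}

#' Blank-based feature filtering
#'
#' A compound is discarded when it is detected (ion counts above the
#' detection threshold) in strictly more than half of the blank
#' measurements.
#'
#' @param features character vector of compound names under consideration.
#' @param blanks data.frame with columns `blank_id`, `compound`,
#'   `ion_counts` (and optionally `kind`).
#' @param count_threshold detection threshold on ion counts (default 300).
#' @param freq_threshold detection-frequency cutoff (default 0.5, strict).
#' @return list with `retained`, `discarded` (character vectors) and
#'   `detection_freq` (named numeric, fraction of blanks with detection).
#' @export
blank_filter <- function(features, blanks, count_threshold = 300,
                         freq_threshold = 0.5) {
  features <- unique(as.character(features))
  if (is.null(blanks) || nrow(blanks) == 0) {
    warning("empty blank set: all features retained")
    return(list(retained = features, discarded = character(0),
                detection_freq = stats::setNames(rep(NA_real_,
                  length(features)), features)))
  }
  stopifnot(all(c("blank_id", "compound", "ion_counts") %in% names(blanks)))
  n_blanks <- length(unique(blanks$blank_id))
  freq <- vapply(features, function(cmp) {
    det <- blanks$compound == cmp & blanks$ion_counts > count_threshold
    # a blank without a record for the compound counts as a non-detection
    length(unique(blanks$blank_id[det])) / n_blanks
  }, numeric(1))
  discarded <- features[freq > freq_threshold]
  list(retained = setdiff(features, discarded), discarded = discarded,
       detection_freq = freq)
}

#' Quantify an instrument response against a calibration curve
#'
#' Back-calculates mass from the calibration line and divides by the
#' sampled matrix volume. Masses below the LOD (including negative
#' back-calculated masses) are reported censored at the LOD, never as
#' negative point estimates; masses between LOD and LOQ are flagged as
#' below quantification but keep their value.
#'
#' @param response instrument response (vectorized).
#' @param curve a [fit_calibration()] object.
#' @param volume sampled volume: litres for water, m^3 for air (scalar > 0).
#' @param matrix `"water"` or `"aerosol"`, sets the output unit
#'   (ng/L or ng/m3).
#' @return data.frame with `mass_ng`, `value`, `unit`, `censor`
#'   (`"none"`, `"lt_loq"`, `"lt_lod"`).
#' @export
quantify <- function(response, curve, volume,
                     matrix = c("water", "aerosol")) {
  matrix <- match.arg(matrix)
  if (!inherits(curve, "calibration_curve")) stop("curve must be a calibration_curve")
  if (!is.numeric(volume) || length(volume) != 1 || volume <= 0) {
    stop("volume must be a single positive number")
  }
  mass <- (response - curve$intercept) / curve$sensitivity
  censor <- rep("none", length(mass))
  censor[mass < curve$loq] <- "lt_loq"
  censor[mass < curve$lod | mass <= 0] <- "lt_lod"
  value <- mass / volume
  value[censor == "lt_lod"] <- curve$lod / volume
  data.frame(mass_ng = mass, value = value,
             unit = if (matrix == "water") "ng/L" else "ng/m3",
             censor = censor, stringsAsFactors = FALSE)
}

#' Convert a calibration curve's detection limits to concentration units
#'
#' @param curve a [fit_calibration()] object.
#' @param volume sampled volume (L for water, m^3 for air).
#' @param matrix `"water"` or `"aerosol"`.
#' @return data.frame with `lod`, `loq`, `unit` in concentration units.
#' @export
lod_from_calibration <- function(curve, volume,
                                 matrix = c("water", "aerosol")) {
  matrix <- match.arg(matrix)
  if (volume <= 0) stop("volume must be positive")
  data.frame(lod = curve$lod / volume, loq = curve$loq / volume,
             unit = if (matrix == "water") "ng/L" else "ng/m3",
             stringsAsFactors = FALSE)
}
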