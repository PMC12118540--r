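#' Aerosolization factors, bubble scavenging and the AF-Kow relationship
#'
#' The aerosolization factor (AF) of a compound is the ratio of its
#' aerosol concentration (pg/m3) to its water concentration (pg/L) in
#' samples collected the same day at the same site, so AF has units of
#' L/m3 and proxies the efficiency of water-to-air transfer. Bubble
#' scavenging is summarized by K_s = K_aq / K_a, the ratio of the aqueous
#' and air adsorption coefficients.
#'
#' @name physchem_enrichment
NULL

#' Per-pair aerosolization factors
#'
#' Pairs same-day, same-site, same-compound water and aerosol samples and
#' computes AF = aerosol (pg/m3) / water (pg/L). Pairs whose water value
#' is censored (or zero) are excluded and counted; `policy = "substitute"`
#' keeps water values censored at the LOD as a sensitivity analysis.
#' Censored aerosol values are likewise excluded under the default policy.
#'
#' @param samples long sample table with `censor` flags; water in ng/L or
#'   pg/L, aerosol in pg/m3 or ng/m3 (converted internally).
#' @param sites site ids to include (default the southern sites).
#' @param policy `"exclude"` or `"substitute"`.
#' @return list with `pairs` (data.frame `compound`, `site`, `date`, `af`)
#'   and `excluded` (data.frame of skipped pairs with `reason`).
#' @export
aerosolization_factor <- function(samples, sites = c("BF", "IB", "SS"),
                                  policy = c("exclude", "substitute")) {
  policy <- match.arg(policy)
  w <- samples[samples$matrix == "water" & samples$site %in% sites, ]
  a <- samples[samples$matrix == "aerosol" & samples$site %in% sites, ]
  if (!"censor" %in% names(w)) w$censor <- "none"
  if (!"censor" %in% names(a)) a$censor <- "none"
  key <- function(d) paste(d$compound, d$site, d$date)
  m <- match(key(a), key(w))
  ok <- !is.na(m)
  a <- a[ok, ]; w <- w[m[ok], ]
  wconc_pgL <- convert_conc(w$value, w$unit[1], "pg/L")
  aconc <- convert_conc(a$value, a$unit[1], "pg/m3")
  reason <- rep(NA_character_, nrow(a))
  if (policy == "exclude") {
    reason[w$censor == "lt_lod"] <- "water_censored"
    reason[a$censor == "lt_lod" & is.na(reason)] <- "aerosol_censored"
  }
  reason[wconc_pgL <= 0 & is.na(reason)] <- "water_nonpositive"
  keep <- is.na(reason)
  pairs <- data.frame(compound = a$compound[keep], site = a$site[keep],
                      date = a$date[keep],
                      af = aconc[keep] / wconc_pgL[keep],
                      stringsAsFactors = FALSE)
  excluded <- data.frame(compound = a$compound[!keep], site = a$site[!keep],
                         date = a$date[!keep], reason = reason[!keep],
                         stringsAsFactors = FALSE)
  list(pairs = pairs, excluded = excluded)
}

#' Bubble scavenging coefficient and regime
#'
#' K_s = K_aq / K_a. With threshold T (default 10): K_s < 1/T means the
#' compound stays in the water ("water_accumulating"), 1/T <= K_s <= T
#' means it collects at the bubble-water interface ("interface"), and
#' K_s > T means it partitions into the bubble interior
#' ("bubble_interior").
#'
#' @param k_a air adsorption coefficient (m, > 0), vectorized.
#' @param k_aq aqueous adsorption coefficient (m, > 0).
#' @param threshold regime threshold T (> 1).
#' @return data.frame `k_s`, `regime`.
#' @export
scavenging_regime <- function(k_a, k_aq, threshold = 10) {
  if (any(k_a <= 0) || any(k_aq <= 0)) {
    stop("adsorption coefficients must be positive")
  }
  stopifnot(threshold > 1)
  k_s <- k_aq / k_a
  regime <- ifelse(k_s < 1 / threshold, "water_accumulating",
                   ifelse(k_s > threshold, "bubble_interior", "interface"))
  data.frame(k_s = k_s, regime = regime, stringsAsFactors = FALSE)
}

#' Four-way surface-activity / scavenging transfer class
#'
#' Combines hydrophobicity (surface activity, log Kow) with bubble
#' scavenging (K_s): compounds that are surface active but poorly
#' scavenged ("surface_only", e.g. high-Kow UV filters) are excluded from
#' the AF-Kow regression because their water-to-air route is not bubble
#' entrainment.
#'
#' @param log_kow vector of log10 octanol-water partition coefficients.
#' @param k_s vector of scavenging coefficients.
#' @param kow_threshold log Kow above which a compound counts as surface
#'   active (default 4).
#' @param threshold K_s regime threshold T; scavenged means
#'   K_s >= 1/T (default 10).
#' @return character vector: `surface_and_scavenged`, `scavenged_only`,
#'   `surface_only` or `neither`.
#' @export
transfer_class <- function(log_kow, k_s, kow_threshold = 4,
                           threshold = 10) {
  surface <- log_kow >= kow_threshold
  scavenged <- k_s >= 1 / threshold
  ifelse(surface & scavenged, "surface_and_scavenged",
         ifelse(!surface & scavenged, "scavenged_only",
                ifelse(surface, "surface_only", "neither")))
}

#' Per-compound enrichment summary
#'
#' Averages AF in log10 space (geometric mean, matching the convention of
#' reporting log-average AFs; arithmetic mean available via
#' `average = "arithmetic"`), joins the physicochemical constants and
#' assigns transfer classes; `excluded_flag` marks compounds left out of
#' the AF-Kow regression.
#'
#' @param af result of [aerosolization_factor()] (or its `$pairs`).
#' @param compounds compound registry with `name`, `log_kow`, `k_a`,
#'   `k_aq`.
#' @param average `"log"` (default) or `"arithmetic"`.
#' @param kow_threshold,threshold passed to [transfer_class()].
#' @return data.frame `compound`, `n_pairs`, `log_af_mean`, `log_af_sd`,
#'   `log_kow`, `k_s`, `regime`, `transfer_class`, `excluded_flag`.
#' @export
summarize_enrichment <- function(af, compounds, average = c("log",
                                                            "arithmetic"),
                                 kow_threshold = 4, threshold = 10) {
  average <- match.arg(average)
  pairs <- if (is.list(af) && !is.data.frame(af)) af$pairs else af
  pairs <- pairs[is.finite(pairs$af) & pairs$af > 0, ]
  sp <- split(pairs$af, pairs$compound)
  cmp <- names(sp)
  log_mean <- vapply(sp, function(v) {
    if (average == "log") mean(log10(v)) else log10(mean(v))
  }, numeric(1))
  log_sd <- vapply(sp, function(v) {
    if (length(v) > 1) stats::sd(log10(v)) else 0
  }, numeric(1))
  i <- match(cmp, compounds$name)
  sr <- scavenging_regime(compounds$k_a[i], compounds$k_aq[i], threshold)
  tc <- transfer_class(compounds$log_kow[i], sr$k_s, kow_threshold,
                       threshold)
  data.frame(compound = cmp, n_pairs = lengths(sp),
             log_af_mean = log_mean, log_af_sd = log_sd,
             log_kow = compounds$log_kow[i], k_s = sr$k_s,
             regime = sr$regime, transfer_class = tc,
             excluded_flag = tc == "surface_only",
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Regression of log AF on log Kow
#'
#' Unweighted OLS of the per-compound mean log10 AF on log10 Kow with free
#' intercept, excluding flagged compounds; an inverse-variance weighted
#' fit is available when per-compound SDs are present.
#'
#' @param records output of [summarize_enrichment()] (needs
#'   `log_af_mean`, `log_kow`, optionally `excluded_flag`, `log_af_sd`).
#' @param weighted logical; weight by 1/log_af_sd^2 where positive.
#' @return object of class `spray_regression` with an extra `slope_se`
#'   element.
#' @export
regress_logaf_logkow <- function(records, weighted = FALSE) {
  r <- records
  if ("excluded_flag" %in% names(r)) r <- r[!r$excluded_flag, ]
  r <- r[is.finite(r$log_af_mean) & is.finite(r$log_kow), ]
  if (nrow(r) < 3) stop("AF-Kow regression needs at least 3 compounds")
  w <- NULL
  if (weighted && "log_af_sd" %in% names(r)) {
    w <- ifelse(r$log_af_sd > 0, 1 / r$log_af_sd^2, NA)
    w[is.na(w)] <- max(w, na.rm = TRUE)
  }
  fit <- stats::lm(log_af_mean ~ log_kow, data = r, weights = w)
  sm <- summary(fit)
  structure(list(
    slope = unname(stats::coef(fit)["log_kow"]),
    intercept = unname(stats::coef(fit)["(Intercept)"]),
    slope_se = sm$coefficients["log_kow", "Std. Error"],
    r_squared = sm$r.squared,
    p_value = sm$coefficients["log_kow", "Pr(>|t|)"],
    n = nrow(r), r2_definition = "centered"
  ), class = "spray_regression")
}
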