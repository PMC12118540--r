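#' Rain-event statistics: detection, windows, regressions, spatial tests
#'
#' @name event_stats
NULL

#' Detect rain events and attach analysis windows
#'
#' Maximal wet runs above an intensity threshold are merged when separated
#' by gaps shorter than `min_gap_h`. Each event carries a dry pre-window
#' (default 2 days before the first wet hour), the wet window, and a
#' post-rain accumulation window (default 3 days after the last wet hour).
#'
#' @param rain data.frame `datetime`, `rain_mmhr` (hourly).
#' @param min_intensity_mm_h wet threshold (an hour is wet when rain >=
#'   this value).
#' @param min_gap_h merge gap, hours (strictly shorter gaps are merged).
#' @param pre_days,accum_days window lengths in days.
#' @return data.frame with one row per event: `event_id`, `pre_start`,
#'   `wet_start`, `wet_end`, `accum_end` (POSIXct). Empty (zero-row) when
#'   there is no rain.
#' @export
detect_events <- function(rain, min_intensity_mm_h = 0.1, min_gap_h = 12,
                          pre_days = 2, accum_days = 3) {
  stopifnot(all(c("datetime", "rain_mmhr") %in% names(rain)))
  wet <- rain$rain_mmhr >= min_intensity_mm_h
  empty <- data.frame(event_id = integer(0),
                      pre_start = as.POSIXct(character(0), tz = "UTC"),
                      wet_start = as.POSIXct(character(0), tz = "UTC"),
                      wet_end = as.POSIXct(character(0), tz = "UTC"),
                      accum_end = as.POSIXct(character(0), tz = "UTC"))
  if (!any(wet)) return(empty)
  r <- rle(wet)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- data.frame(start = starts[r$values], end = ends[r$values])
  # merge runs separated by dry gaps shorter than min_gap_h
  merged <- runs[1, , drop = FALSE]
  if (nrow(runs) > 1) {
    for (i in 2:nrow(runs)) {
      gap <- runs$start[i] - merged$end[nrow(merged)] - 1
      if (gap < min_gap_h) {
        merged$end[nrow(merged)] <- runs$end[i]
      } else {
        merged <- rbind(merged, runs[i, ])
      }
    }
  }
  t <- rain$datetime
  data.frame(
    event_id = seq_len(nrow(merged)),
    pre_start = t[merged$start] - pre_days * 86400,
    wet_start = t[merged$start],
    wet_end = t[merged$end],
    accum_end = t[merged$end] + accum_days * 86400
  )
}

# internal: the set of sample dates falling in each window of an event
event_window_dates <- function(event,
                               window = c("pre", "wet", "accumulation")) {
  window <- match.arg(window)
  switch(window,
    pre = seq(as.Date(event$pre_start, tz = "UTC"),
              as.Date(event$wet_start, tz = "UTC") - 1, by = "day"),
    wet = seq(as.Date(event$wet_start, tz = "UTC"),
              as.Date(event$wet_end, tz = "UTC"), by = "day"),
    accumulation = seq(as.Date(event$wet_end, tz = "UTC") + 1,
                       as.Date(event$accum_end, tz = "UTC"), by = "day")
  )
}

#' Pre/post concentration change for one event
#'
#' Delta = mean over the post window (wet or accumulation) minus mean over
#' the dry pre-window, with the SD propagated in quadrature from the
#' standard errors of the two window means.
#'
#' @param event one row of [detect_events()] output.
#' @param series daily data.frame `date`, `value`.
#' @param post `"accumulation"` (default) or `"wet"`.
#' @return list with `delta`, `sd`, `n_pre`, `n_post`.
#' @export
event_deltas <- function(event, series,
                         post = c("accumulation", "wet")) {
  post <- match.arg(post)
  stopifnot(all(c("date", "value") %in% names(series)))
  win_mean <- function(window) {
    v <- series$value[series$date %in% event_window_dates(event, window)]
    v <- v[!is.na(v)]
    if (length(v) == 0) {
      stop("no samples in ", window, " window of event ", event$event_id)
    }
    s <- if (length(v) > 1) stats::sd(v) / sqrt(length(v)) else 0
    list(mean = mean(v), se = s, n = length(v))
  }
  pre <- win_mean("pre")
  pst <- win_mean(post)
  list(delta = pst$mean - pre$mean, sd = sqrt(pre$se^2 + pst$se^2),
       n_pre = pre$n, n_post = pst$n)
}

#' Linear regression with optional forced zero intercept
#'
#' Free-intercept fits are ordinary least squares with the conventional
#' R-squared and a two-sided slope p-value. Forced-zero fits use the
#' closed-form slope `sum(x*y)/sum(x^2)`; their r-squared is reported as
#' the squared Pearson correlation between observed and fitted values
#' (recorded in `$r2_definition`; the uncentered definition
#' `1 - RSS/sum(y^2)` is available via `uncentered_r2 = TRUE`).
#'
#' @param x,y numeric vectors (n >= 2 pairs after NA removal).
#' @param force_zero_intercept logical.
#' @param uncentered_r2 logical; only used for forced-zero fits.
#' @return object of class `spray_regression`: list with `slope`,
#'   `intercept`, `r_squared`, `p_value`, `n`, `r2_definition`.
#' @export
regress <- function(x, y, force_zero_intercept = FALSE,
                    uncentered_r2 = FALSE) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 2) stop("regression needs at least 2 complete pairs")
  if (force_zero_intercept) {
    if (all(x == 0)) stop("forced-zero regression undefined when all x are 0")
    slope <- sum(x * y) / sum(x^2)
    fitted <- slope * x
    r2 <- if (uncentered_r2) {
      if (all(y == 0)) NA_real_ else 1 - sum((y - fitted)^2) / sum(y^2)
    } else if (stats::sd(y) == 0 || stats::sd(fitted) == 0) {
      NA_real_
    } else {
      stats::cor(y, fitted)^2
    }
    fit <- stats::lm(y ~ x + 0)
    p <- tryCatch(summary(fit)$coefficients["x", "Pr(>|t|)"],
                  error = function(e) NA_real_)
    res <- list(slope = slope, intercept = 0, r_squared = r2, p_value = p,
                n = length(x),
                r2_definition = if (uncentered_r2) "uncentered"
                                else "squared_pearson_obs_vs_fitted")
  } else {
    fit <- stats::lm(y ~ x)
    sm <- summary(fit)
    p <- tryCatch(sm$coefficients["x", "Pr(>|t|)"],
                  error = function(e) NA_real_)
    res <- list(slope = unname(stats::coef(fit)["x"]),
                intercept = unname(stats::coef(fit)["(Intercept)"]),
                r_squared = sm$r.squared, p_value = p, n = length(x),
                r2_definition = "centered")
  }
  structure(res, class = "spray_regression")
}

#' @export
print.spray_regression <- function(x, ...) {
  cat(sprintf("slope %.4g, intercept %.4g, R2 %.3f, p %.3g, n %d (%s)\n",
              x$slope, x$intercept, x$r_squared, x$p_value, x$n,
              x$r2_definition))
  invisible(x)
}

# internal: correlation strength label per the conventional r2 bands
strength_band <- function(r2) {
  ifelse(is.na(r2), NA_character_,
         ifelse(r2 > 0.7, "strong", ifelse(r2 >= 0.4, "moderate", "weak")))
}

#' Forced-zero regressions of aerosol pollutants on a sewage tracer
#'
#' For every non-tracer compound, same-day same-site aerosol values across
#' the selected sites are regressed on the tracer with the intercept fixed
#' at zero. Pairs with a censored member are excluded by default;
#' `policy = "substitute"` keeps them at their reported detection-limit
#' values (the plotting convention for below-quantification points).
#' Sites where the tracer is entirely censored are dropped with a warning.
#'
#' @param samples long sample table with censor flags.
#' @param tracer tracer compound name (default "benzoylecgonine").
#' @param sites site ids to pool (default the southern sites).
#' @param policy `"exclude"` or `"substitute"`.
#' @return data.frame: `compound`, `slope`, `r_squared`, `p_value`, `n`,
#'   `censored_n`, `strength`.
#' @export
tracer_correlations <- function(samples, tracer = "benzoylecgonine",
                                sites = c("BF", "IB", "SS"),
                                policy = c("exclude", "substitute")) {
  policy <- match.arg(policy)
  a <- samples[samples$matrix == "aerosol" & samples$site %in% sites, ]
  if (!tracer %in% a$compound) stop("tracer not present in table")
  tr <- a[a$compound == tracer, ]
  for (s in unique(tr$site)) {
    if (all(tr$censor[tr$site == s] == "lt_lod")) {
      warning("tracer entirely censored at site ", s, "; site dropped")
      a <- a[a$site != s, ]
      tr <- tr[tr$site != s, ]
    }
  }
  others <- setdiff(unique(a$compound), tracer)
  key <- function(d) paste(d$site, d$date)
  res <- lapply(others, function(cmp) {
    cc <- a[a$compound == cmp, ]
    m <- match(key(cc), key(tr))
    ok <- !is.na(m)
    x <- tr$value[m[ok]]; y <- cc$value[ok]
    cens <- tr$censor[m[ok]] == "lt_lod" | cc$censor[ok] == "lt_lod"
    if (policy == "exclude") {
      x <- x[!cens]; y <- y[!cens]
    }
    if (length(x) < 2) {
      return(data.frame(compound = cmp, slope = NA_real_,
                        r_squared = NA_real_, p_value = NA_real_,
                        n = length(x), censored_n = sum(cens),
                        strength = NA_character_,
                        stringsAsFactors = FALSE))
    }
    r <- regress(x, y, force_zero_intercept = TRUE)
    data.frame(compound = cmp, slope = r$slope, r_squared = r$r_squared,
               p_value = r$p_value, n = r$n, censored_n = sum(cens),
               strength = strength_band(r$r_squared),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

# internal: exact two-sided permutation distribution of the Mann-Whitney U
# via dynamic programming over doubled midranks (handles ties exactly)
mw_exact_p <- function(ranks2, n1, u_obs, n2) {
  total <- sum(ranks2)
  # counts[k+1, s+1] = number of size-k subsets with doubled-rank sum s
  counts <- matrix(0, nrow = n1 + 1, ncol = total + 1)
  counts[1, 1] <- 1
  for (r in ranks2) {
    for (k in n1:1) {
      nz <- which(counts[k, ] > 0)
      if (length(nz)) {
        counts[k + 1, nz + r] <- counts[k + 1, nz + r] + counts[k, nz]
      }
    }
  }
  sums2 <- which(counts[n1 + 1, ] > 0) - 1
  freq <- counts[n1 + 1, sums2 + 1]
  u_all <- sums2 / 2 - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  dev <- abs(u_obs - mu)
  sum(freq[abs(u_all - mu) >= dev - 1e-9]) / sum(freq)
}

#' Mann-Whitney U comparison of two groups
#'
#' Two-sided Mann-Whitney U test. The p-value comes from exact permutation
#' enumeration (tie-aware, via a rank-sum counting recursion) when
#' `n1 * n2 <= 400`, and from the tie-corrected normal approximation with
#' continuity correction otherwise.
#'
#' @param values_a,values_b numeric vectors, each of length >= 3.
#' @return list with `U` (statistic for the first group), `p_value`,
#'   `method`.
#' @export
site_compare <- function(values_a, values_b) {
  values_a <- values_a[is.finite(values_a)]
  values_b <- values_b[is.finite(values_b)]
  n1 <- length(values_a); n2 <- length(values_b)
  if (n1 < 3 || n2 < 3) stop("each group needs at least 3 values")
  r <- rank(c(values_a, values_b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  if (n1 * n2 <= 400) {
    p <- mw_exact_p(round(2 * r), n1, U, n2)
    method <- "exact_permutation"
  } else {
    N <- n1 + n2
    ties <- table(c(values_a, values_b))
    sigma2 <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (abs(U - n1 * n2 / 2) - 0.5) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-max(z, 0)))
    method <- "normal_tie_corrected"
  }
  list(U = U, p_value = p, method = method)
}

#' Classify each sampling day by local wind origin and wetness
#'
#' A day is `onshore` when strictly more than 75% of its non-missing hours
#' blow from the ocean sector, `offshore` when strictly less than 25% do,
#' and `mixed` otherwise (the 75% edge is mixed by convention). Days with
#' more than 25% missing hours are `unknown`. A day is wet when any hour
#' records rain.
#'
#' @param wind data.frame `datetime`, `wind_dir_deg` (degrees, direction
#'   the wind blows from).
#' @param rain data.frame `datetime`, `rain_mmhr`.
#' @param onshore_sector numeric length 2, `c(from, to)` degrees; winds
#'   with `from <= dir < to` count as onshore (default `c(180, 360)`, an
#'   ocean to the west of a north-south coastline).
#' @return data.frame `date`, `wind_class`
#'   (onshore/offshore/mixed/unknown), `wet`.
#' @export
classify_airmass <- function(wind, rain, onshore_sector = c(180, 360)) {
  stopifnot(all(c("datetime", "wind_dir_deg") %in% names(wind)))
  d <- as.Date(wind$datetime, tz = "UTC")
  onshore <- wind$wind_dir_deg >= onshore_sector[1] &
    wind$wind_dir_deg < onshore_sector[2]
  res <- lapply(split(seq_along(d), d), function(idx) {
    dir <- onshore[idx]
    n <- length(idx)
    miss <- sum(is.na(dir))
    if (miss / n > 0.25) return("unknown")
    f <- mean(dir, na.rm = TRUE)
    if (f > 0.75) "onshore" else if (f < 0.25) "offshore" else "mixed"
  })
  rd <- as.Date(rain$datetime, tz = "UTC")
  wet_days <- unique(rd[rain$rain_mmhr > 0])
  data.frame(date = as.Date(names(res)),
             wind_class = unlist(res, use.names = FALSE),
             wet = as.Date(names(res)) %in% wet_days,
             stringsAsFactors = FALSE)
}

#' Extract a daily site/compound series from a long sample table
#'
#' @param samples long table.
#' @param site,compound,matrix selectors.
#' @param drop_censored drop `lt_lod` rows (default FALSE).
#' @return data.frame `date`, `value`.
#' @export
daily_series <- function(samples, site, compound,
                         matrix = c("water", "aerosol"),
                         drop_censored = FALSE) {
  matrix <- match.arg(matrix)
  x <- samples[samples$site == site & samples$compound == compound &
                 samples$matrix == matrix, ]
  if (drop_censored && "censor" %in% names(x)) {
    x <- x[x$censor != "lt_lod", ]
  }
  x <- x[order(x$date), ]
  data.frame(date = x$date, value = x$value)
}
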