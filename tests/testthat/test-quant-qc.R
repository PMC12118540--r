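test_that("noiseless calibration gives exact sensitivity and zero LOD", {
  lv <- CALIBRATION_LEVELS_NG
  cal <- suppressWarnings(fit_calibration(lv, 2 * lv))
  expect_equal(cal$sensitivity, 2, tolerance = 1e-12)
  expect_equal(cal$intercept, 0, tolerance = 1e-10)
  expect_equal(cal$lod, 0, tolerance = 1e-10)
  expect_equal(cal$loq, (10 / 3) * cal$lod)
})

test_that("intercept SE matches the closed-form OLS oracle", {
  # fixed 3-point curve with known residuals; oracle computed from the
  # normal-equations formulas, independent of lm
  x <- c(1.37, 13.7, 137)
  y <- c(3.0, 28.1, 273.5)
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  b1 <- sum((x - mean(x)) * (y - mean(y))) / sxx
  b0 <- mean(y) - b1 * mean(x)
  s2 <- sum((y - b0 - b1 * x)^2) / (n - 2)
  se_b0 <- sqrt(s2 * (1 / n + mean(x)^2 / sxx))
  cal <- fit_calibration(x, y)
  expect_equal(cal$sensitivity, b1, tolerance = 1e-12)
  expect_equal(cal$intercept, b0, tolerance = 1e-12)
  expect_equal(cal$intercept_se, se_b0, tolerance = 1e-12)
  expect_equal(cal$lod, 3 * se_b0 / b1, tolerance = 1e-12)
})

test_that("degenerate calibrations are rejected", {
  expect_error(fit_calibration(c(1, 10), c(2, 20)), "fewer than 3")
  expect_error(fit_calibration(c(1, 1, 1), c(2, 2.1, 1.9)), "fewer than 3")
  expect_error(fit_calibration(c(1, 10, 100), c(5, 5, 5)),
               "all responses equal")
  expect_error(fit_calibration(c(1, 10, 100), c(100, 50, 2)),
               "non-positive sensitivity")
})

test_that("LOD scales with intercept error and inversely with sensitivity", {
  set.seed(42)
  x <- c(1.37, 13.7, 137, 50)
  for (i in 1:10) {
    y <- 3 * x + rnorm(4, 0, 2)
    base <- fit_calibration(x, y)
    # scaling all responses scales sensitivity and SE together: LOD fixed
    sc <- fit_calibration(x, 5 * y)
    expect_equal(sc$lod, base$lod, tolerance = 1e-9)
    # inflating residuals about the fitted line scales the SE, hence LOD
    fitted <- base$intercept + base$sensitivity * x
    infl <- fit_calibration(x, fitted + 3 * (y - fitted))
    expect_equal(infl$lod, 3 * base$lod, tolerance = 1e-9)
  }
})

test_that("blank filter applies the >300-count, >50%-of-blanks rule", {
  blanks <- data.frame(
    blank_id = rep(c("b1", "b2", "b3"), each = 3),
    compound = rep(c("caffeine", "cocaine", "heroin"), times = 3),
    ion_counts = c(350, 350, 250,   350, 100, 250,   100, 100, 250)
  )
  # caffeine: >300 in 2/3 blanks (66.7%) -> discarded
  # cocaine:  >300 in 1/3 blanks (33.3%) -> retained
  # heroin:   250 everywhere (below threshold) -> retained
  res <- blank_filter(c("caffeine", "cocaine", "heroin"), blanks)
  expect_equal(res$discarded, "caffeine")
  expect_setequal(res$retained, c("cocaine", "heroin"))

  # exactly 50% is retained (strict inequality)
  b2 <- data.frame(blank_id = c("b1", "b2"), compound = "x",
                   ion_counts = c(400, 10))
  expect_equal(blank_filter("x", b2)$retained, "x")

  # idempotent and order-independent
  res2 <- blank_filter(res$retained, blanks)
  expect_setequal(res2$retained, res$retained)
  shuf <- blanks[sample(nrow(blanks)), ]
  expect_setequal(blank_filter(c("caffeine", "cocaine", "heroin"),
                               shuf)$discarded, res$discarded)

  expect_warning(out <- blank_filter("x", blanks[0, ]), "empty blank set")
  expect_equal(out$retained, "x")
})

test_that("quantification back-calculates mass and flags censoring", {
  lv <- CALIBRATION_LEVELS_NG
  cal <- suppressWarnings(fit_calibration(lv, 2 * lv)) # slope 2, lod 0
  # 1.37 ng in 1 L of water is 1.37 ppt
  q <- quantify(2 * 1.37, cal, volume = 1, matrix = "water")
  expect_equal(q$value, 1.37, tolerance = 1e-9)
  expect_equal(q$unit, "ng/L")
  expect_equal(q$censor, "none")
  # 137 ng over a 23.5 h filter at 50 L/min (70.5 m3)
  qa <- quantify(2 * 137, cal, volume = 50 * 60 * 23.5 / 1000,
                 matrix = "aerosol")
  expect_equal(qa$value, 137 / 70.5, tolerance = 1e-9)
  expect_equal(qa$unit, "ng/m3")
  # response at the intercept: zero mass, censored
  expect_equal(quantify(0, cal, 1)$censor, "lt_lod")

  # noisy curve: negative back-calculated mass reports the LOD, never a
  # negative value
  cal2 <- fit_calibration(c(1.37, 13.7, 137), c(4, 29, 276))
  qn <- quantify(cal2$intercept - 5, cal2, volume = 1)
  expect_equal(qn$censor, "lt_lod")
  expect_equal(qn$value, cal2$lod)
  expect_true(qn$value >= 0)

  expect_error(quantify(10, cal, volume = 0), "positive")
})

test_that("quantify inverts the response map above the LOQ", {
  cal <- fit_calibration(c(1.37, 13.7, 137), c(4, 29, 276))
  mass <- c(5, 20, 120)
  resp <- cal$intercept + cal$sensitivity * mass
  out <- quantify(resp, cal, volume = 2)
  expect_equal(out$mass_ng, mass, tolerance = 1e-9)
  expect_equal(out$value, mass / 2, tolerance = 1e-9)
  expect_true(all(out$censor[mass > cal$loq] == "none"))
})
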