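test_that("analytic AUC matches closed forms and a dense trapezoid oracle", {
  # flat curve: C0 = Cinf = c integrates to c*T
  flat <- structure(
    list(model = "SK", c0 = 7,
         fractions = tibble(c_inf = 7, k = 0.02, t_start = 0),
         data = tibble(time_min = 0:10, value = rep(7, 11))),
    class = "kinetics_fit")
  expect_equal(auc_analytic(flat, 120), 7 * 120)

  fit <- fit_sk(sk_curve(c0 = 0, c_inf = 50, k = 0.02))
  expect_equal(auc_analytic(fit, 180), 6568.31, tolerance = 1e-5)

  # dense-grid trapezoid oracle agrees to 0.01%
  dense <- sk_curve(c0 = 0, c_inf = 50, k = 0.02, times = seq(0, 180, 0.001))
  expect_equal(auc_analytic(fit, 180), auc_trapezoid(dense, 180),
               tolerance = 1e-4)

  # monotone in the horizon
  aucs <- vapply(c(90, 120, 180), function(T) auc_analytic(fit, T), numeric(1))
  expect_true(all(diff(aucs) > 0))
})

test_that("CPS AUC sums per-fraction closed forms from each onset", {
  fit <- fit_cps(cps_curve(), 2)
  dense <- cps_curve(times = seq(0, 180, 0.001))
  expect_equal(auc_analytic(fit, 180), auc_trapezoid(dense, 180),
               tolerance = 1e-4)
  # horizon before the second onset only sees the first fraction
  fit1 <- fit_sk(sk_curve(c_inf = 30, k = 0.1))
  expect_equal(auc_analytic(fit, 20), auc_analytic(fit1, 20), tolerance = 1e-3)
})

test_that("trapezoid AUC handles simple geometries and refuses extrapolation", {
  tri <- tibble(time_min = c(0, 10), value = c(0, 10))
  expect_equal(auc_trapezoid(tri, 10), 50)
  rect <- tibble(time_min = c(0, 60), value = c(4, 4))
  expect_equal(auc_trapezoid(rect, 60), 240)
  # leading flat segment when t=0 absent; interpolation at T
  part <- tibble(time_min = c(10, 30), value = c(2, 6))
  expect_equal(auc_trapezoid(part, 20), 10 * 2 + (2 + 4) / 2 * 10)
  expect_error(auc_trapezoid(tri, 11), "auc_analytic")
})

test_that("correlation screen reproduces the printed GI-GL agreement", {
  feats <- tibble(sample_id = as.character(1:8), gl = table3_gl)
  scr <- correlation_screen(feats, gi = table3_gi)
  expect_equal(round(scr$r_vs_gi^2, 3), 0.933)
  expect_equal(scr$stars_gi, "**")
})

test_that("correlation screen handles exact linearity, self-correlation and scaling", {
  x <- c(1, 2, 3)
  scr <- correlation_screen(tibble(sample_id = letters[1:3], f = x),
                            gi = 2 * x)
  expect_equal(scr$r_vs_gi, 1, tolerance = 1e-12)
  expect_lt(scr$p_gi, 1e-6)

  set.seed(5)
  a <- rnorm(8); b <- rnorm(8)
  r0 <- correlation_screen(tibble(sample_id = letters[1:8], f = a), gi = b)$r_vs_gi
  r1 <- correlation_screen(tibble(sample_id = letters[1:8], f = 3 * a - 7),
                           gi = 0.5 * b + 2)$r_vs_gi
  expect_equal(r0, r1, tolerance = 1e-12)

  # zero-variance feature flagged, not fatal
  scr0 <- correlation_screen(tibble(sample_id = letters[1:4], f = rep(1, 4)),
                             gi = 1:4)
  expect_true(is.na(scr0$r_vs_gi))
  expect_equal(scr0$note, "zero variance")
})

test_that("significance stars follow the two-level convention", {
  expect_equal(gikit:::significance_stars(c(0.004, 0.03, 0.2)),
               c("**", "*", ""))
})

test_that("calibration recovers an exact line and matches the normal equations", {
  x <- c(500, 1200, 2600, 3400)
  # an exact line trips lm's "essentially perfect fit" warning; that is the point
  exact <- suppressWarnings(
    fit_calibration(tibble(aucr180 = x, gi = 1.834 + 0.009 * x)))
  expect_equal(exact$intercept, 1.834, tolerance = 1e-10)
  expect_equal(exact$slope, 0.009, tolerance = 1e-12)
  expect_equal(exact$r_squared, 1, tolerance = 1e-10)

  set.seed(11)
  y <- rnorm(4, 10, 3)
  m <- fit_calibration(tibble(aucr180 = x, gi = y))
  # closed-form OLS oracle
  b <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  a <- mean(y) - b * mean(x)
  expect_equal(m$slope, b, tolerance = 1e-12)
  expect_equal(m$intercept, a, tolerance = 1e-12)

  expect_error(fit_calibration(tibble(aucr180 = rep(1, 4), gi = 1:4)),
               "constant")
})

test_that("calibration slope is recovered on average across noisy studies", {
  set.seed(202)
  slopes <- replicate(500, {
    aucr <- runif(8, 500, 3500) + rnorm(8, 0, 50)
    gi <- 1.834 + 0.009 * aucr + rnorm(8, 0, 1)
    fit_calibration(tibble(aucr180 = aucr, gi = gi))$slope
  })
  expect_lt(abs(mean(slopes) - 0.009) / 0.009, 0.05)
})

test_that("eGI prediction applies the line and its new-observation SE", {
  eq7 <- calibration_model(1.834, 0.009)
  expect_equal(predict_egi(eq7, 1000)$egi, 10.834)
  eq8 <- calibration_model(6.101, 0.009)
  expect_equal(predict_egi(eq8, 0)$egi, 6.101)

  set.seed(3)
  x <- runif(8, 500, 3500)
  m <- fit_calibration(tibble(aucr180 = x, gi = 1.834 + 0.009 * x + rnorm(8)))
  # zero-leverage check at the calibration mean
  p <- predict_egi(m, m$x_mean)
  expect_equal(p$egi_sd, m$residual_se * sqrt(1 + 1 / m$n), tolerance = 1e-12)
  # replicate SD adds in quadrature
  p2 <- predict_egi(m, m$x_mean, aucr180_sd = 100)
  expect_equal(p2$egi_sd,
               sqrt(p$egi_sd^2 + (m$slope * 100)^2), tolerance = 1e-12)
  expect_error(predict_egi(m, -5), "non-negative")
})

test_that("calibration models survive a JSON round-trip", {
  set.seed(8)
  x <- runif(6, 500, 3000)
  m <- fit_calibration(tibble(aucr180 = x, gi = 2 + 0.01 * x + rnorm(6)),
                       protocol = "PANCREATIN", basis = "REDUCING_SUGAR_NORMALIZED")
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration(m, path)
  back <- read_calibration(path)
  for (f in c("intercept", "slope", "r_squared", "n", "residual_se",
              "se_intercept", "se_slope", "x_mean", "x_ss")) {
    expect_equal(back[[f]], m[[f]], tolerance = 1e-12, label = f)
  }
  p <- predict_egi(back, 1500)
  expect_equal(p$egi, m$intercept + m$slope * 1500)
  expect_true(is.finite(p$egi_sd))
})

test_that("error rate reproduces the printed validation arithmetic", {
  expect_equal(error_rate(9, 12.30), 36.67)
  expect_equal(error_rate(52, 39.96), 23.15)
  expect_equal(error_rate(30, 49.11), 63.70)
  expect_equal(error_rate(28, 20.81), 25.68)
  expect_equal(error_rate(30, 41.20), 37.33)
  expect_equal(error_rate(19, 19.07), 0.37)
  expect_equal(error_rate(42, 42), 0)
  expect_error(error_rate(0, 10), "positive")
})
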