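test_that("LOS of exact first-order data is linear with slope -k", {
  # dense 1-min grid: finite differences carry only the sinh correction,
  # so a regression through the LOS points recovers -k almost exactly
  curve <- sk_curve(c0 = 0, c_inf = 40, k = 0.03, times = 0:240)
  los <- los_transform(curve)
  expect_equal(los$n_dropped, 0)
  reg <- lm(ln_slope ~ t_mid, data = los$points)
  expect_gt(summary(reg)$r.squared, 0.999)
  expect_equal(unname(coef(reg)[2]), -0.03, tolerance = 0.005)
  # intercept oracle: ln(k Cinf) + ln(sinh(k/2)/(k/2)) for unit spacing
  expect_equal(unname(coef(reg)[1]),
               log(0.03 * 40) + log(sinh(0.03 / 2) / (0.03 / 2)),
               tolerance = 1e-6)
})

test_that("LOS drops non-positive increments and errors on flat series", {
  flat <- tibble(time_min = c(0, 10, 20, 30), value = rep(5, 4))
  expect_error(los_transform(flat), "insufficient LOS points")
  wiggly <- tibble(time_min = c(0, 10, 20, 30, 40), value = c(0, 5, 4, 8, 10))
  los <- los_transform(wiggly)
  expect_equal(los$n_dropped, 1)
  expect_equal(nrow(los$points), 3)
  expect_true(all(is.finite(los$points$ln_slope)))
})

test_that("count_fractions finds one fraction for SK and two for separated CPS", {
  los1 <- count_fractions(los_transform(sk_curve()))
  expect_equal(los1$n_fractions, 1L)
  expect_equal(nrow(los1$segments), 1)
  expect_lt(los1$segments$slope, 0)

  los2 <- count_fractions(los_transform(cps_curve()))
  expect_equal(los2$n_fractions, 2L)
  expect_true(all(diff(los2$segments$slope) > 0))  # later phase slower

  # oracle: exhaustive breakpoint search minimizing total RSS picks the
  # same split as the BIC winner on noiseless CPS data
  pts <- dplyr::arrange(los_transform(cps_curve())$points, t_mid)
  n <- nrow(pts)
  rss_of <- function(cut) {
    f1 <- lm(ln_slope ~ t_mid, data = pts[1:cut, ])
    f2 <- lm(ln_slope ~ t_mid, data = pts[(cut + 1):n, ])
    sum(f1$residuals^2) + sum(f2$residuals^2)
  }
  cuts <- 3:(n - 3)
  best_cut <- cuts[which.min(vapply(cuts, rss_of, numeric(1)))]
  expect_equal(los2$segments$n_points[1], best_cut)
})

test_that("count_fractions falls back to one fraction on short inputs", {
  short <- sk_curve(times = c(5, 10, 15, 20, 30))  # 4 LOS points
  los <- count_fractions(los_transform(short))
  expect_equal(los$n_fractions, 1L)
})

test_that("SK fit recovers noiseless generating parameters", {
  fit <- fit_sk(sk_curve(c0 = 0, c_inf = 40, k = 0.03))
  expect_true(fit$converged)
  expect_equal(fit$fractions$k, 0.03, tolerance = 1e-6)
  expect_equal(fit$fractions$c_inf, 40, tolerance = 1e-6)
  expect_lt(fit$c0, 1e-5)
  expect_gt(fit$r_squared, 1 - 1e-10)
  # nonzero baseline too
  fit2 <- fit_sk(sk_curve(c0 = 3, c_inf = 35, k = 0.015))
  expect_equal(fit2$c0, 3, tolerance = 1e-5)
  expect_equal(fit2$fractions$c_inf, 35, tolerance = 1e-5)
})

test_that("SK estimates are unbiased under assay noise and beat the truth in RSS", {
  t <- digestion_schedule("SINGLE_ENZYME")
  truth <- 40 * (1 - exp(-0.03 * t))
  set.seed(42)
  ks <- numeric(200)
  for (i in 1:200) {
    v <- pmax(truth + rnorm(length(t), 0, 0.5), 0)
    fit <- fit_sk(tibble(time_min = t, value = v))
    ks[i] <- fit$fractions$k
    # least squares must be at least as good as the generating curve
    rss_fit <- sum((v - predict(fit, t))^2)
    rss_truth <- sum((v - truth)^2)
    expect_lte(rss_fit, rss_truth + 1e-8)
  }
  expect_lt(abs(mean(ks) - 0.03), 0.002)
})

test_that("SK bias shrinks with the noise level", {
  t <- digestion_schedule("SINGLE_ENZYME")
  truth <- 40 * (1 - exp(-0.03 * t))
  bias_at <- function(sd) {
    set.seed(99)
    mean(replicate(60, {
      v <- pmax(truth + rnorm(length(t), 0, sd), 0)
      fit_sk(tibble(time_min = t, value = v))$fractions$k
    })) - 0.03
  }
  biases <- abs(vapply(c(1.0, 0.5, 0.1), bias_at, numeric(1)))
  expect_lt(biases[3], biases[1] + 1e-4)
  expect_lt(biases[3], 5e-4)
})

test_that("CPS fit recovers a noiseless two-fraction curve", {
  fit <- fit_cps(cps_curve(), n_fractions = 2)
  expect_true(fit$converged)
  expect_equal(fit$fractions$c_inf, c(30, 20), tolerance = 1e-4)
  expect_equal(fit$fractions$k, c(0.1, 0.01), tolerance = 1e-4)
  expect_equal(fit$fractions$t_start, c(0, 30), tolerance = 1e-4)
  expect_lt(fit$c0, 1e-3)
})

test_that("CPS reduces to SK and nests it in RSS", {
  curve <- cps_curve()
  expect_equal(fit_cps(curve, 1), fit_sk(curve))
  rss <- function(f) sum((curve$value - predict(f, curve$time_min))^2)
  expect_lte(rss(fit_cps(curve, 2)), rss(fit_sk(curve)) + 1e-8)
})

test_that("fitted curves start at C0 and are non-decreasing", {
  for (fit in list(fit_sk(sk_curve(c0 = 2)), fit_cps(cps_curve(), 2))) {
    expect_equal(predict(fit, 0), fit$c0, tolerance = 1e-12)
    grid <- predict(fit, seq(0, 240, by = 0.5))
    expect_true(all(diff(grid) > -1e-10))
  }
})

test_that("fraction counting discriminates SK from CPS under noise", {
  t <- digestion_schedule("SINGLE_ENZYME")
  sk_truth <- 40 * (1 - exp(-0.03 * t))
  cps_truth <- cps_curve()$value
  count <- function(v) {
    tryCatch(
      suppressMessages(
        count_fractions(los_transform(tibble(time_min = t, value = v)))$n_fractions),
      error = function(e) NA_integer_)
  }
  set.seed(123)
  sk_ok <- cps_ok <- 0
  for (i in 1:100) {
    if (identical(count(pmax(sk_truth + rnorm(10, 0, 0.3), 0)), 1L)) sk_ok <- sk_ok + 1
    if (identical(count(pmax(cps_truth + rnorm(10, 0, 0.3), 0)), 2L)) cps_ok <- cps_ok + 1
  }
  expect_gte(sk_ok, 95)
  expect_gte(cps_ok, 95)
})

test_that("tidy and glance summarize fits; fit_kinetics handles tables", {
  fit <- fit_sk(sk_curve())
  td <- tidy(fit)
  expect_equal(td$term, c("c0", "c_inf", "k", "t_start"))
  gl <- glance(fit)
  expect_equal(gl$model, "SK")
  expect_true(gl$converged)

  d <- bind_rows(as_digesto_table(sk_curve(), replicate = 1),
                 as_digesto_table(sk_curve(c_inf = 42), replicate = 2))
  fits <- fit_kinetics(d)
  expect_equal(nrow(fits), 2)
  expect_equal(fits$model, c("SK", "SK"))
  expect_equal(fits$c_inf_1, c(40, 42), tolerance = 1e-5)

  pooled <- fit_kinetics(d, pool_replicates = TRUE)
  expect_equal(nrow(pooled), 1)
  expect_equal(pooled$c_inf_1, 41, tolerance = 0.2)
})
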