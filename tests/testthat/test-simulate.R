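test_that("the generator is exact without noise and deterministic with it", {
  fr <- tibble(c_inf = 40, k = 0.03, t_start = 0)
  d0 <- simulate_digestogram(fr, noise_sd = 0, n_replicates = 1)
  t <- digestion_schedule("SINGLE_ENZYME")
  expect_equal(d0$value, 40 * (1 - exp(-0.03 * t)), tolerance = 1e-15)
  expect_equal(d0$time_min, t)

  d1 <- simulate_digestogram(fr, noise_sd = 0.5, seed = 77)
  d2 <- simulate_digestogram(fr, noise_sd = 0.5, seed = 77)
  expect_identical(d1, d2)
  d3 <- simulate_digestogram(fr, noise_sd = 0.5, seed = 78)
  expect_false(identical(d1$value, d3$value))
})

test_that("generated noise has the configured per-timepoint spread", {
  fr <- tibble(c_inf = 40, k = 0.03, t_start = 0)
  d <- simulate_digestogram(fr, noise_sd = 0.5, n_replicates = 1000, seed = 4)
  sds <- d %>%
    group_by(time_min) %>%
    summarise(sd = sd(value), .groups = "drop") %>%
    pull(sd)
  expect_true(all(sds > 0.45 & sds < 0.55))
  expect_true(all(d$value >= 0))
})

test_that("INFOGEST schedule is honoured and custom schedules validated", {
  fr <- tibble(c_inf = 30, k = 0.05, t_start = 0)
  d <- simulate_digestogram(fr, schedule = "INFOGEST_INTESTINAL",
                            noise_sd = 0, n_replicates = 1,
                            protocol = "INFOGEST")
  expect_equal(d$time_min, c(0, 5, 10, 15, 20, 30, 60, 90, 120))
  expect_error(simulate_digestogram(fr, schedule = c(10, 5, 20)),
               "strictly increasing")
})

test_that("absorbance inversion round-trips through the conversion chain", {
  meta <- tibble(sample_id = "S1", clinical_gi = 12, sample_mass_mg = 300,
                 total_starch_pct_db = 10, total_carb_pct = 20)
  d <- simulate_digestogram(tibble(c_inf = 8, k = 0.02, t_start = 0),
                            noise_sd = 0, n_replicates = 1)
  abs_tbl <- simulate_absorbance_series(d, meta)
  back <- convert_absorbance(abs_tbl, meta, basis = "REDUCING_SUGAR_NORMALIZED")
  expect_equal(back$value, d$value, tolerance = 1e-9)

  # the standard's absorbance cancels out of the ratio
  abs2 <- simulate_absorbance_series(d, meta, dA_standard = 2.4)
  back2 <- convert_absorbance(abs2, meta, basis = "REDUCING_SUGAR_NORMALIZED")
  expect_equal(back2$value, d$value, tolerance = 1e-9)

  # percent-starch basis round-trips too
  dp <- d %>% mutate(basis = "PERCENT_STARCH")
  absp <- simulate_absorbance_series(dp, meta)
  backp <- convert_absorbance(absp, meta, basis = "PERCENT_STARCH")
  expect_equal(backp$value, dp$value, tolerance = 1e-9)
})

test_that("noise propagates linearly through the conversion", {
  meta <- tibble(sample_id = "S1", sample_mass_mg = 300,
                 total_starch_pct_db = 10, total_carb_pct = 20)
  d <- simulate_digestogram(tibble(c_inf = 8, k = 0.02, t_start = 0),
                            noise_sd = 0.4, n_replicates = 400, seed = 9)
  abs_tbl <- simulate_absorbance_series(d, meta)
  # dA = value * carb_mg / (100 * mw * dilution * vol_L / dA_std):
  # a fixed linear factor, so SDs scale by the same factor
  factor <- abs_tbl$dA_sample[1] / d$value[1]
  sd_abs <- abs_tbl %>% group_by(time_min) %>%
    summarise(s = sd(dA_sample), .groups = "drop") %>% pull(s)
  sd_val <- d %>% group_by(time_min) %>%
    summarise(s = sd(value), .groups = "drop") %>% pull(s)
  expect_equal(sd_abs, sd_val * factor, tolerance = 1e-9)
})

test_that("a noiseless calibration study is exactly identifiable end to end", {
  st <- simulate_calibration_study(n_samples = 6, gi_noise_sd = 0,
                                   digestogram_noise_sd = 0, n_replicates = 1,
                                   seed = 31)
  # each generated curve's analytic AUC equals its target
  for (i in seq_len(6)) {
    fit <- structure(
      list(model = "SK", c0 = 0,
           fractions = tibble(c_inf = st$truth$c_inf[i],
                              k = st$truth$k[i], t_start = 0)),
      class = "kinetics_fit")
    expect_equal(auc_analytic(fit, 180), st$truth$aucr180_target[i],
                 tolerance = 1e-6)
  }
  aucr <- st$digestograms %>%
    group_by(sample_id) %>%
    summarise(aucr180 = auc_analytic(fit_sk(dplyr::pick(time_min, value)), 180),
              .groups = "drop") %>%
    left_join(st$meta, by = "sample_id")
  m <- fit_calibration(aucr, "aucr180", "clinical_gi")
  expect_equal(m$intercept, 1.834, tolerance = 1e-4)
  expect_equal(m$slope, 0.009, tolerance = 1e-5)
  expect_equal(m$r_squared, 1, tolerance = 1e-8)
})

test_that("study generation is seed-reproducible and respects invariants", {
  s1 <- simulate_calibration_study(seed = 12)
  s2 <- simulate_calibration_study(seed = 12)
  expect_identical(s1, s2)
  expect_true(all(s1$truth$k >= 0.005 & s1$truth$k <= 0.05))
  expect_true(all(s1$truth$aucr180_target >= 500 &
                    s1$truth$aucr180_target <= 3500))
  expect_true(all(s1$digestograms$value >= 0))
  expect_error(simulate_calibration_study(n_samples = 3), "at least 4")
})

test_that("write_simulation emits re-readable CSVs and a truth JSON", {
  st <- simulate_calibration_study(n_samples = 4, seed = 2)
  dir <- withr::local_tempdir()
  write_simulation(st, dir)
  d <- read_digestion_table(file.path(dir, "digestograms.csv"), "digestogram")
  expect_equal(as.data.frame(d), as.data.frame(st$digestograms),
               tolerance = 1e-12)
  a <- read_digestion_table(file.path(dir, "absorbance.csv"), "absorbance")
  expect_equal(nrow(a), nrow(st$digestograms))
  truth <- jsonlite::read_json(file.path(dir, "truth.json"),
                               simplifyVector = TRUE)
  expect_equal(truth$k, st$truth$k, tolerance = 1e-12)
})
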