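#' Analytic area under a fitted digestion curve
#'
#' Closed-form AUC of a first-order fit over `[0, T]`. For the SK model
#' `C(t) = C0 + (Cinf - C0)(1 - e^{-kt})` this is
#' `Cinf * T - (Cinf - C0)(1 - e^{-kT}) / k`; for CPS fits the per-fraction
#' closed forms over `[t_start, T]` are summed. Computing AUC from the
#' fitted curve (rather than the raw points) allows horizons beyond the
#' last sampled time — e.g. a 180-min AUC from the 0--120 min INFOGEST
#' schedule.
#'
#' @param fit A `kinetics_fit` from [fit_sk()] or [fit_cps()].
#' @param T_min Integration horizon in minutes (> 0); commonly 90, 120
#'   or 180.
#' @return AUC in (value units) x min.
#' @examples
#' t <- digestion_schedule("SINGLE_ENZYME")
#' fit <- fit_sk(tibble::tibble(time_min = t, value = 50 * (1 - exp(-0.02 * t))))
#' auc_analytic(fit, 180)  # ~6568.31
#' @export
auc_analytic <- function(fit, T_min) {
  stopifnot(inherits(fit, "kinetics_fit"))
  if (T_min <= 0) abort("T_min must be positive.")
  if (any(fit$fractions$k <= 0)) abort("All rate coefficients must be positive.")
  amps <- fraction_amplitudes(fit$model, fit$c0, fit$fractions)
  auc <- fit$c0 * T_min
  for (j in seq_len(nrow(fit$fractions))) {
    ts <- fit$fractions$t_start[j]
    if (T_min <= ts) next
    dt <- T_min - ts
    k <- fit$fractions$k[j]
    auc <- auc + amps[j] * (dt - (1 - exp(-k * dt)) / k)
  }
  auc
}

#' Trapezoidal area under observed digestogram points
#'
#' Trapezoidal rule over the observed points up to `T_min`, linearly
#' interpolating at `T_min` when it falls between observations. If the
#' series does not start at t = 0, a leading flat segment at the first
#' observed value is assumed. Raw-data cross-check for [auc_analytic()];
#' no extrapolation beyond the last observation is performed.
#'
#' @param curve A single digestion curve (`time_min`, `value`).
#' @param T_min Horizon in minutes, at most `max(time_min)`.
#' @return AUC in (value units) x min.
#' @export
auc_trapezoid <- function(curve, T_min) {
  curve <- arrange(as_tibble(curve), .data$time_min)
  t <- curve$time_min
  v <- curve$value
  if (T_min > max(t)) {
    abort(paste0("T_min exceeds the last observed time (", max(t),
                 " min); use auc_analytic() on a fitted curve instead."))
  }
  if (t[1] > 0) {   # leading flat segment from t = 0
    t <- c(0, t)
    v <- c(v[1], v)
  }
  keep <- t <= T_min
  tt <- t[keep]
  vv <- v[keep]
  if (max(tt) < T_min) {  # interpolate the partial last trapezoid
    vT <- stats::approx(t, v, xout = T_min)$y
    tt <- c(tt, T_min)
    vv <- c(vv, vT)
  }
  sum(diff(tt) * (head(vv, -1) + tail(vv, -1)) / 2)
}

#' AUC summary metrics for fitted curves
#'
#' Computes analytic AUCs at the requested horizons for every row of a
#' [fit_kinetics()] table, in long format.
#'
#' @param fits Output of [fit_kinetics()] (needs the `fit` list-column).
#' @param horizons AUC horizons in minutes (default 90, 120, 180).
#' @return Long tibble: keys, `horizon_T`, `auc`, `method`.
#' @export
auc_metrics <- function(fits, horizons = c(90, 120, 180)) {
  purrr::map_dfr(seq_len(nrow(fits)), function(i) {
    f <- fits$fit[[i]]
    tibble(
      sample_id = fits$sample_id[i], protocol = fits$protocol[i],
      basis = fits$basis[i], replicate = fits$replicate[i],
      horizon_T = horizons,
      auc = vapply(horizons, function(T) auc_analytic(f, T), numeric(1)),
      method = "ANALYTIC"
    )
  })
}

significance_stars <- function(p) {
  dplyr::case_when(is.na(p) ~ NA_character_,
                   p < 0.01 ~ "**",
                   p < 0.05 ~ "*",
                   TRUE ~ "")
}

#' Pearson correlation screen of digestion parameters against GI and GL
#'
#' Correlates each candidate digestion summary (AUC at several horizons,
#' rate coefficient k, plateau Cinf, on either value basis) with the
#' clinical GI and the glycemic load across samples: Pearson r with a
#' two-sided t test on n - 2 degrees of freedom. Stars follow the usual
#' convention (`**` p < 0.01, `*` p < 0.05), on raw p values by default;
#' `p_adjust = "holm"` applies a Holm correction before starring.
#'
#' @param features Tibble of per-sample parameter values: column
#'   `sample_id` plus one numeric column per parameter (optionally
#'   `protocol`/`basis` key columns, carried through).
#' @param gi,gl Named or positional numeric vectors aligned with
#'   `features$sample_id`.
#' @param p_adjust `"none"` (default) or any method of [stats::p.adjust()].
#' @return Tibble with one row per parameter: `parameter`, `r_vs_gi`,
#'   `p_gi`, `stars_gi`, `r_vs_gl`, `p_gl`, `stars_gl`, `n`. Zero-variance
#'   parameters yield `NA` correlations and are flagged in `note`.
#' @examples
#' correlation_screen(
#'   tibble::tibble(sample_id = letters[1:4], k = c(.01, .02, .03, .05)),
#'   gi = c(9, 11, 13, 30), gl = c(1.3, 2.4, 2.4, 4.8))
#' @export
correlation_screen <- function(features, gi, gl = NULL, p_adjust = "none") {
  features <- as_tibble(features)
  key_cols <- intersect(c("sample_id", "protocol", "basis"), names(features))
  params <- setdiff(names(features), key_cols)
  n <- nrow(features)
  if (n < 3) abort("Need at least 3 paired observations.")
  if (length(gi) != n) abort("gi must have one value per feature row.")

  one_target <- function(x, y) {
    if (sd(x) == 0 || sd(y) == 0) {
      return(list(r = NA_real_, p = NA_real_, note = "zero variance"))
    }
    ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
    list(r = unname(ct$estimate), p = ct$p.value, note = "")
  }

  out <- purrr::map_dfr(params, function(pm) {
    x <- features[[pm]]
    a <- one_target(x, gi)
    row <- tibble(parameter = pm, r_vs_gi = a$r, p_gi = a$p, n = n, note = a$note)
    if (!is.null(gl)) {
      b <- one_target(x, gl)
      row$r_vs_gl <- b$r
      row$p_gl <- b$p
      if (nzchar(b$note)) row$note <- b$note
    }
    row
  })
  if (p_adjust != "none") {
    out$p_gi <- stats::p.adjust(out$p_gi, method = p_adjust)
    if (!is.null(gl)) out$p_gl <- stats::p.adjust(out$p_gl, method = p_adjust)
  }
  out$stars_gi <- significance_stars(out$p_gi)
  if (!is.null(gl)) out$stars_gl <- significance_stars(out$p_gl)
  cols <- c("parameter", "r_vs_gi", "p_gi", "stars_gi",
            if (!is.null(gl)) c("r_vs_gl", "p_gl", "stars_gl"), "n", "note")
  out[, cols]
}

#' Calibrate the linear GI prediction model
#'
#' Ordinary least squares of clinical GI on the 180-min reducing-sugar AUC
#' (AUCR180): `GI = a + b * AUCR180`. The fitted line, its R-squared,
#' residual standard error and coefficient standard errors form the
#' calibration that [predict_egi()] applies to new samples.
#'
#' @param data Data frame with the calibration samples.
#' @param aucr180,gi Column names (unquoted or character) of the predictor
#'   and response; defaults `aucr180` and `gi`.
#' @param protocol,basis Optional labels stored with the model.
#' @return An object of class `gi_calibration`.
#' @examples
#' d <- tibble::tibble(aucr180 = c(500, 1500, 2500, 3500),
#'                     gi = 1.834 + 0.009 * c(500, 1500, 2500, 3500))
#' fit_calibration(d)
#' @export
fit_calibration <- function(data, aucr180 = "aucr180", gi = "gi",
                            protocol = NA_character_, basis = NA_character_) {
  data <- as_tibble(data)
  x <- data[[aucr180]]
  y <- data[[gi]]
  if (is.null(x) || is.null(y)) abort("Predictor/response columns not found.")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("Calibration needs at least 3 samples.")
  if (sd(x) == 0) abort("Calibration predictor is constant.")
  fit <- lm(y ~ x)
  sm <- summary(fit)
  structure(
    list(
      intercept = unname(coef(fit)[1]), slope = unname(coef(fit)[2]),
      r_squared = sm$r.squared, n = n,
      residual_se = sm$sigma,
      se_intercept = sm$coefficients[1, 2],
      se_slope = sm$coefficients[2, 2],
      x_mean = mean(x), x_ss = sum((x - mean(x))^2),
      protocol = protocol, basis = basis, lm = fit
    ),
    class = "gi_calibration"
  )
}

#' @export
print.gi_calibration <- function(x, ...) {
  cat(sprintf("<gi_calibration> GI = %.3f + %.4g x AUCR180 (R^2 = %.3f, n = %d)\n",
              x$intercept, x$slope, x$r_squared, x$n))
  invisible(x)
}

#' @rdname tidy.gi_calibration
#' @method glance gi_calibration
#' @export
glance.gi_calibration <- function(x, ...) {
  tibble(r.squared = x$r_squared, sigma = x$residual_se, nobs = x$n,
         protocol = x$protocol, basis = x$basis)
}

#' Tidy a GI calibration
#'
#' @param x A `gi_calibration`.
#' @param ... Unused.
#' @return `tidy()`: one row per coefficient with standard errors;
#'   `glance()`: one-row model summary.
#' @method tidy gi_calibration
#' @export
tidy.gi_calibration <- function(x, ...) {
  tibble(term = c("(Intercept)", "aucr180"),
         estimate = c(x$intercept, x$slope),
         std.error = c(x$se_intercept, x$se_slope))
}

#' Build a calibration object from published coefficients
#'
#' Constructs a `gi_calibration` directly from a known intercept and
#' slope (e.g. a previously published prediction equation) so it can be
#' applied with [predict_egi()] without the original calibration data.
#' Prediction uncertainty requires the fit statistics; when omitted,
#' `predict_egi()` returns point predictions with `NA` uncertainty.
#'
#' @param intercept,slope Line coefficients (GI units; GI per AUC unit).
#' @param r_squared,n,residual_se,se_intercept,se_slope,x_mean,x_ss
#'   Optional fit statistics.
#' @param protocol,basis Optional labels.
#' @return A `gi_calibration`.
#' @examples
#' pancreatin_eq <- calibration_model(1.834, 0.009)
#' predict_egi(pancreatin_eq, 1000)$egi  # 10.834
#' @export
calibration_model <- function(intercept, slope, r_squared = NA_real_,
                              n = NA_integer_, residual_se = NA_real_,
                              se_intercept = NA_real_, se_slope = NA_real_,
                              x_mean = NA_real_, x_ss = NA_real_,
                              protocol = NA_character_, basis = NA_character_) {
  structure(
    list(intercept = intercept, slope = slope, r_squared = r_squared,
         n = n, residual_se = residual_se, se_intercept = se_intercept,
         se_slope = se_slope, x_mean = x_mean, x_ss = x_ss,
         protocol = protocol, basis = basis, lm = NULL),
    class = "gi_calibration"
  )
}

#' Serialize / read a calibration model as JSON
#'
#' @param model A `gi_calibration`.
#' @param path JSON file path.
#' @return `write_calibration()` returns `path` invisibly;
#'   `read_calibration()` returns the `gi_calibration`.
#' @export
write_calibration <- function(model, path) {
  stopifnot(inherits(model, "gi_calibration"))
  fields <- model[c("protocol", "basis", "intercept", "slope", "r_squared",
                    "n", "residual_se", "se_intercept", "se_slope",
                    "x_mean", "x_ss")]
  jsonlite::write_json(fields, path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(path)
}

#' @rdname write_calibration
#' @export
read_calibration <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  null2na <- function(x) if (is.null(x)) NA_real_ else x
  calibration_model(
    intercept = j$intercept, slope = j$slope,
    r_squared = null2na(j$r_squared), n = null2na(j$n),
    residual_se = null2na(j$residual_se),
    se_intercept = null2na(j$se_intercept), se_slope = null2na(j$se_slope),
    x_mean = null2na(j$x_mean), x_ss = null2na(j$x_ss),
    protocol = if (is.null(j$protocol)) NA_character_ else j$protocol,
    basis = if (is.null(j$basis)) NA_character_ else j$basis
  )
}

#' Predict estimated GI from a calibrated model
#'
#' Applies `eGI = a + b * AUCR180` and attaches a prediction uncertainty:
#' the OLS standard error for a new observation,
#' `s * sqrt(1 + 1/n + (x - x_mean)^2 / Sxx)`, combined in quadrature with
#' the propagated replicate spread `b * aucr180_sd` when supplied.
#'
#' @param model A `gi_calibration`.
#' @param aucr180 New AUCR180 value(s), >= 0.
#' @param aucr180_sd Optional replicate SD of each AUCR180.
#' @param sample_id Optional identifiers carried into the result.
#' @param clinical_gi Optional known GI; when present the relative error
#'   rate versus the prediction is reported.
#' @return Tibble with `sample_id`, `aucr180`, `egi`, `egi_sd`, and when
#'   `clinical_gi` is given, `clinical_gi` and `error_rate_pct`.
#' @examples
#' m <- calibration_model(6.101, 0.009)
#' predict_egi(m, 0)$egi  # 6.101
#' @export
predict_egi <- function(model, aucr180, aucr180_sd = NULL,
                        sample_id = NULL, clinical_gi = NULL) {
  stopifnot(inherits(model, "gi_calibration"))
  if (any(aucr180 < 0, na.rm = TRUE)) abort("aucr180 must be non-negative.")
  egi <- model$intercept + model$slope * aucr180
  if (is.finite(model$residual_se) && is.finite(model$x_ss) && model$x_ss > 0) {
    se_new <- model$residual_se *
      sqrt(1 + 1 / model$n + (aucr180 - model$x_mean)^2 / model$x_ss)
  } else {
    se_new <- rep(NA_real_, length(egi))
  }
  if (!is.null(aucr180_sd)) {
    prop <- abs(model$slope) * aucr180_sd
    se_new <- ifelse(is.na(se_new), prop, sqrt(se_new^2 + prop^2))
  }
  out <- tibble(
    sample_id = sample_id %||% paste0("sample_", seq_along(egi)),
    aucr180 = aucr180, egi = egi, egi_sd = se_new
  )
  if (!is.null(clinical_gi)) {
    out$clinical_gi <- clinical_gi
    out$error_rate_pct <- error_rate(clinical_gi, egi)
  }
  out
}

#' Relative prediction error rate
#'
#' `|eGI - GI| / GI x 100`, the validation statistic comparing a predicted
#' eGI against the clinically measured GI, reported to 2 decimals.
#'
#' @param clinical_gi Clinical GI (> 0), vectorized.
#' @param egi Predicted eGI.
#' @return Error rate in percent (2 dp).
#' @examples
#' error_rate(9, 12.30)   # 36.67
#' error_rate(52, 39.96)  # 23.15
#' @export
error_rate <- function(clinical_gi, egi) {
  if (any(clinical_gi <= 0, na.rm = TRUE)) abort("clinical_gi must be positive.")
  round(abs(egi - clinical_gi) / clinical_gi * 100, 2)
}
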