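#' Logarithm-of-slope (LOS) transform of a digestogram
#'
#' For first-order digestion `C(t) = C0 + (Cinf - C0)(1 - e^{-kt})` the log
#' of the time derivative is linear in time:
#' `ln(dC/dt) = ln(k (Cinf - C0)) - k t`. The LOS transform estimates the
#' derivative by finite differences between consecutive timepoints,
#' `(C_{i+1} - C_i) / (t_{i+1} - t_i)`, places each log-slope at the
#' interval midpoint, and drops intervals with non-positive increments
#' (the log is undefined there; assay noise makes them common near the
#' plateau). Linear segments in the resulting plot indicate first-order
#' digestible fractions.
#'
#' @param curve A single digestion curve: data frame with `time_min` and
#'   `value` (use [digestogram_curve()] to extract one from a long table),
#'   with at least 3 timepoints.
#' @return An object of class `los_result`: list with `points` (tibble
#'   `t_mid`, `ln_slope`), `n_dropped` (intervals excluded), `segments`
#'   (empty until [count_fractions()] is applied) and `n_fractions` (`NA`
#'   until then).
#' @seealso [count_fractions()] to infer the number of digestible fractions.
#' @export
los_transform <- function(curve) {
  curve <- as_tibble(curve)
  if (!all(c("time_min", "value") %in% names(curve))) {
    abort("`curve` needs columns time_min and value.")
  }
  curve <- arrange(curve, .data$time_min)
  if (nrow(curve) < 3) abort("LOS transform needs at least 3 timepoints.")
  t <- curve$time_min
  v <- curve$value
  dt <- diff(t)
  dv <- diff(v)
  if (any(dt <= 0)) abort("Timepoints must be strictly increasing.")
  keep <- dv > 0
  n_dropped <- sum(!keep)
  if (sum(keep) < 2) abort("insufficient LOS points (fewer than 2 positive increments)")
  pts <- tibble(
    t_mid = (t[-length(t)] + t[-1])[keep] / 2,
    ln_slope = log(dv[keep] / dt[keep])
  )
  structure(
    list(points = pts, n_dropped = n_dropped,
         segments = empty_segments(), n_fractions = NA_integer_),
    class = "los_result"
  )
}

empty_segments <- function() {
  tibble(segment = integer(), slope = double(), intercept = double(),
         t_start = double(), t_end = double(), n_points = integer(),
         r_squared = double())
}

#' @export
print.los_result <- function(x, ...) {
  cat("<los_result>", nrow(x$points), "points,", x$n_dropped, "dropped")
  if (!is.na(x$n_fractions)) {
    cat(";", x$n_fractions, "digestible fraction(s)")
  }
  cat("\n")
  invisible(x)
}

# Enumerate contiguous partitions of n points into nseg segments of >= minpts.
segment_partitions <- function(n, nseg, minpts = 3) {
  if (nseg == 1) return(list(c(0, n)))
  out <- list()
  recurse <- function(start, left, acc) {
    if (left == 1) {
      if (n - start >= minpts) out[[length(out) + 1]] <<- c(acc, n)
      return(invisible())
    }
    for (cut in seq(start + minpts, n - minpts * (left - 1))) {
      recurse(cut, left - 1, c(acc, cut))
    }
  }
  recurse(0, nseg, 0)
  out
}

fit_segmented_los <- function(pts, cuts) {
  # cuts: boundaries c(0, i1, ..., n); returns segments tibble + total RSS
  segs <- empty_segments()
  rss <- 0
  for (s in seq_len(length(cuts) - 1)) {
    idx <- (cuts[s] + 1):cuts[s + 1]
    sub <- pts[idx, ]
    fit <- lm(ln_slope ~ t_mid, data = sub)
    res <- sum(fit$residuals^2)
    tss <- sum((sub$ln_slope - mean(sub$ln_slope))^2)
    segs <- bind_rows(segs, tibble(
      segment = s,
      slope = coef(fit)[["t_mid"]],
      intercept = coef(fit)[["(Intercept)"]],
      t_start = min(sub$t_mid), t_end = max(sub$t_mid),
      n_points = nrow(sub),
      r_squared = if (tss > 0) 1 - res / tss else NA_real_
    ))
    rss <- rss + res
  }
  list(segments = segs, rss = rss)
}

#' Count digestible fractions from a LOS plot
#'
#' Fits 1..`max_fractions` ordered linear segments to the LOS points, with
#' breakpoints restricted to observed midpoints, each segment holding at
#' least 3 points and a negative slope (first-order decay). The segment
#' count is selected by the Bayesian information criterion on the LOS
#' residuals; ties break toward fewer segments. A single linear LOS plot
#' means one homogeneous digestible fraction (SK model); distinct segments
#' indicate rapidly and slowly digested substrate pools (CPS model).
#'
#' Multi-segment candidates must be physically interpretable as distinct
#' first-order phases: slopes ordered from steepest (rapidly digestible)
#' to shallowest, with consecutive rate constants differing by at least
#' `min_rate_ratio` — phases closer in rate than that are not resolvable
#' as separate linear stretches of a LOS plot.
#'
#' When fewer than 4 points are available for a multi-segment hypothesis,
#' or no multi-segment candidate satisfies the constraints, the result
#' falls back to one fraction with a message.
#'
#' @param los A [los_transform()] result.
#' @param max_fractions Maximum number of segments to consider (default 2).
#' @param min_rate_ratio Minimum ratio of consecutive segments' decay
#'   rates (|slope_j| / |slope_{j+1}|) for a multi-segment candidate
#'   (default 3).
#' @return The `los_result` with `segments` and `n_fractions` filled.
#' @export
count_fractions <- function(los, max_fractions = 2, min_rate_ratio = 3) {
  stopifnot(inherits(los, "los_result"))
  pts <- arrange(los$points, .data$t_mid)
  n <- nrow(pts)

  candidates <- list()
  for (nseg in seq_len(max_fractions)) {
    if (n < 3 * nseg || (nseg > 1 && n < 4)) next
    best <- NULL
    for (cuts in segment_partitions(n, nseg, minpts = 3)) {
      f <- fit_segmented_los(pts, cuts)
      if (any(f$segments$slope >= 0)) next   # first-order decay only
      if (nseg > 1) {
        sl <- f$segments$slope
        if (any(diff(sl) <= 0)) next         # later phases must be slower
        if (any(sl[-length(sl)] / sl[-1] < min_rate_ratio)) next
      }
      if (is.null(best) || f$rss < best$rss) best <- f
    }
    if (is.null(best)) next
    # BIC on gaussian LOS residuals: 2 line params per segment + breakpoints
    p <- 2 * nseg + (nseg - 1)
    bic <- n * log(max(best$rss, 1e-12) / n) + p * log(n)
    candidates[[length(candidates) + 1]] <-
      list(nseg = nseg, bic = bic, segments = best$segments)
  }

  if (!length(candidates)) {
    # fallback: one unconstrained segment
    inform("LOS segmentation preconditions unmet; falling back to one fraction.")
    f <- fit_segmented_los(pts, c(0, n))
    los$segments <- f$segments
    los$n_fractions <- 1L
    return(los)
  }
  bics <- vapply(candidates, `[[`, numeric(1), "bic")
  nsegs <- vapply(candidates, `[[`, numeric(1), "nseg")
  best <- candidates[[order(bics, nsegs)[1]]]   # tie -> fewer segments
  los$segments <- best$segments
  los$n_fractions <- as.integer(best$nseg)
  los
}

# SK stores c_inf as the curve's asymptote (C0 <= c_inf); CPS fractions are
# per-fraction amplitudes added on top of C0. This returns amplitudes.
fraction_amplitudes <- function(model, c0, fractions) {
  if (identical(model, "SK")) fractions$c_inf - c0 else fractions$c_inf
}

new_kinetics_fit <- function(model, c0, fractions, curve, converged) {
  amps <- mutate(fractions, c_inf = fraction_amplitudes(model, c0, fractions))
  pred <- kinetics_curve(c0, amps, curve$time_min)
  res <- curve$value - pred
  tss <- sum((curve$value - mean(curve$value))^2)
  structure(
    list(model = model, c0 = c0, fractions = fractions,
         r_squared = if (tss > 0) 1 - sum(res^2) / tss else NA_real_,
         rmse = sqrt(mean(res^2)), converged = converged,
         n_points = nrow(curve), data = curve),
    class = "kinetics_fit"
  )
}

# Forward model: first-order fractions, later ones switched on at t_start.
kinetics_curve <- function(c0, fractions, t) {
  out <- rep(c0, length(t))
  for (j in seq_len(nrow(fractions))) {
    ts <- fractions$t_start[j]
    act <- t > ts
    out[act] <- out[act] +
      fractions$c_inf[j] * (1 - exp(-fractions$k[j] * (t[act] - ts)))
  }
  out
}

#' Evaluate a fitted digestion curve
#'
#' @param object A [fit_sk()] or [fit_cps()] result.
#' @param t Times (minutes) at which to evaluate the fitted model.
#' @param ... Unused.
#' @return Fitted digestion extent at `t`.
#' @export
predict.kinetics_fit <- function(object, t = object$data$time_min, ...) {
  amps <- mutate(object$fractions,
                 c_inf = fraction_amplitudes(object$model, object$c0,
                                             object$fractions))
  kinetics_curve(object$c0, amps, t)
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat("<kinetics_fit>", x$model, "model,", nrow(x$fractions), "fraction(s)\n")
  cat("  C0 =", signif(x$c0, 5), "\n")
  for (j in seq_len(nrow(x$fractions))) {
    cat(sprintf("  fraction %d: Cinf = %.5g, k = %.5g /min, t_start = %.4g min\n",
                j, x$fractions$c_inf[j], x$fractions$k[j], x$fractions$t_start[j]))
  }
  cat(sprintf("  R^2 = %.4f, RMSE = %.4g, converged = %s, n = %d\n",
              x$r_squared, x$rmse, x$converged, x$n_points))
  invisible(x)
}

#' @rdname tidy.kinetics_fit
#' @method glance kinetics_fit
#' @export
glance.kinetics_fit <- function(x, ...) {
  tibble(model = x$model, n_fractions = nrow(x$fractions),
         r.squared = x$r_squared, rmse = x$rmse,
         converged = x$converged, nobs = x$n_points)
}

#' Tidy a kinetics fit
#'
#' `tidy()` returns one row per parameter; `glance()` one row of fit
#' summaries.
#'
#' @param x A `kinetics_fit`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy kinetics_fit
#' @export
tidy.kinetics_fit <- function(x, ...) {
  bind_rows(
    tibble(term = "c0", fraction = NA_integer_, estimate = x$c0),
    purrr::map_dfr(seq_len(nrow(x$fractions)), function(j) {
      tibble(term = c("c_inf", "k", "t_start"), fraction = j,
             estimate = c(x$fractions$c_inf[j], x$fractions$k[j],
                          x$fractions$t_start[j]))
    })
  )
}

# Default k starting value from the single-segment LOS slope, else fallback.
los_k_init <- function(curve, fallback = 0.02) {
  k0 <- tryCatch({
    los <- los_transform(curve)
    f <- lm(ln_slope ~ t_mid, data = los$points)
    -coef(f)[["t_mid"]]
  }, error = function(e) fallback)
  if (!is.finite(k0) || k0 <= 0) k0 <- fallback
  min(max(k0, 1e-5), 10)
}

# Bounded Levenberg-Marquardt on a residual function; returns coefficients,
# RSS and a convergence flag (nls.lm info codes 1-3).
lm_fit <- function(resid_fn, start, lower, upper) {
  out <- minpack.lm::nls.lm(
    par = pmin(pmax(start, lower), upper), lower = lower, upper = upper,
    fn = resid_fn,
    control = minpack.lm::nls.lm.control(maxiter = 500, ftol = 1e-12,
                                         ptol = 1e-12))
  list(coef = out$par, rss = out$deviance, conv = out$info %in% 1:3)
}

sk_nls <- function(curve, start, vmax) {
  # parameterized as c0 + dc (1 - e^{-kt}) so Cinf = c0 + dc >= c0
  resid_fn <- function(p) {
    curve$value - (p[["c0"]] + p[["dc"]] * (1 - exp(-p[["k"]] * curve$time_min)))
  }
  lm_fit(resid_fn, unlist(start),
         lower = c(c0 = 0, dc = 0, k = 1e-8),
         upper = c(c0 = vmax, dc = 3 * vmax, k = 10))
}

#' Fit the single first-order kinetics (SK) model
#'
#' Least-squares fit of `C(t) = C0 + (Cinf - C0)(1 - e^{-kt})`: one
#' digestible fraction with rate coefficient `k` (1/min), initial digested
#' amount `C0` and plateau `Cinf` (no substrate left). Bounds:
#' `k` in (0, 10], `C0` in `[0, max(value)]`, `Cinf >= C0`. The default
#' start takes `C0` from the first observation, `Cinf` from the maximum,
#' and `k` from the LOS-plot slope when obtainable (else 0.02/min). If the
#' optimizer fails to converge, two further starts with `k` spanning a
#' 10-fold range are tried; the best attempt is returned with
#' `converged = FALSE` rather than an error.
#'
#' @param curve A single digestion curve (`time_min`, `value`), >= 4 points.
#' @param init Optional named list overriding the start (`c0`, `c_inf`, `k`).
#' @return A `kinetics_fit` with one fraction (`t_start = 0`).
#' @examples
#' t <- digestion_schedule("SINGLE_ENZYME")
#' curve <- tibble::tibble(time_min = t, value = 40 * (1 - exp(-0.03 * t)))
#' fit_sk(curve)
#' @export
fit_sk <- function(curve, init = NULL) {
  curve <- arrange(as_tibble(curve), .data$time_min)
  if (nrow(curve) < 4) abort("SK fit needs at least 4 timepoints.")
  if (sd(curve$value) == 0) abort("SK fit needs non-constant values.")
  vmax <- max(curve$value)
  c0_0 <- min(max(curve$value[1], 0), vmax)
  cinf_0 <- vmax
  k_0 <- los_k_init(curve)
  if (!is.null(init)) {
    c0_0 <- init$c0 %||% c0_0
    cinf_0 <- init$c_inf %||% cinf_0
    k_0 <- init$k %||% k_0
  }
  starts <- list(c(c0 = c0_0, dc = max(cinf_0 - c0_0, 1e-6), k = k_0))
  # multi-start fallbacks spanning a 10-fold k range
  for (mult in c(1 / sqrt(10), sqrt(10))) {
    starts[[length(starts) + 1]] <-
      c(c0 = c0_0, dc = max(cinf_0 - c0_0, 1e-6),
        k = min(max(k_0 * mult, 1e-8), 10))
  }

  best <- NULL
  for (si in seq_along(starts)) {
    fit <- tryCatch(sk_nls(curve, starts[[si]], vmax), error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$rss < best$rss - 1e-12) best <- fit
    if (fit$conv && si == 1L) break  # default start converged; skip multi-start
  }
  if (is.null(best)) {
    fr <- tibble(c_inf = cinf_0, k = k_0, t_start = 0)
    return(new_kinetics_fit("SK", c0_0, fr, curve, converged = FALSE))
  }
  cf <- best$coef
  fr <- tibble(c_inf = cf[["c0"]] + cf[["dc"]], k = cf[["k"]], t_start = 0)
  new_kinetics_fit("SK", cf[["c0"]], fr, curve, converged = best$conv)
}

# CPS forward model on a named parameter vector (c0, c1..cn, k1..kn, t2..tn).
cps_model_value <- function(p, t, n_fractions) {
  out <- rep(p[["c0"]], length(t)) + p[["c1"]] * (1 - exp(-p[["k1"]] * t))
  for (j in 2:n_fractions) {
    ts <- p[[paste0("t", j)]]
    act <- t > ts
    out[act] <- out[act] +
      p[[paste0("c", j)]] * (1 - exp(-p[[paste0("k", j)]] * (t[act] - ts)))
  }
  out
}

#' Fit the combined parallel-and-sequential (CPS) kinetics model
#'
#' Multi-fraction first-order model: a rapidly digested fraction starting
#' at t = 0 plus later fractions that switch on at free onset times,
#' `C(t) = C0 + sum_j Cinf_j (1 - e^{-k_j (t - t_jstart)}) 1[t > t_jstart]`
#' with `t_1start = 0`. Onset times are searched over a multi-start grid of
#' interior observed times and refined by bounded Levenberg-Marquardt.
#' With `n_fractions = 1` the model reduces to the SK model and
#' [fit_sk()] is called directly.
#'
#' @param curve A single digestion curve (`time_min`, `value`), with at
#'   least `3 + 3 * n_fractions` points for `n_fractions >= 2`.
#' @param n_fractions Number of digestible fractions (from
#'   [count_fractions()]).
#' @return A `kinetics_fit` with fractions ordered by onset time.
#' @export
fit_cps <- function(curve, n_fractions = 2) {
  if (n_fractions < 1) abort("n_fractions must be >= 1.")
  if (n_fractions == 1) return(fit_sk(curve))
  curve <- arrange(as_tibble(curve), .data$time_min)
  if (nrow(curve) < 3 + 3 * n_fractions) {
    abort(sprintf("CPS fit with %d fractions needs at least %d points.",
                  n_fractions, 3 + 3 * n_fractions))
  }
  vmax <- max(curve$value)
  tmax <- max(curve$time_min)
  k_0 <- los_k_init(curve)
  resid_fn <- function(p) {
    curve$value - cps_model_value(as.list(p), curve$time_min, n_fractions)
  }

  lower <- c(c0 = 0, setNames(rep(0, n_fractions), paste0("c", 1:n_fractions)),
             setNames(rep(1e-8, n_fractions), paste0("k", 1:n_fractions)))
  upper <- c(c0 = vmax, setNames(rep(3 * vmax, n_fractions), paste0("c", 1:n_fractions)),
             setNames(rep(10, n_fractions), paste0("k", 1:n_fractions)))
  if (n_fractions >= 2) {
    lower <- c(lower, setNames(rep(1e-6, n_fractions - 1), paste0("t", 2:n_fractions)))
    upper <- c(upper, setNames(rep(tmax * (1 - 1e-6), n_fractions - 1),
                               paste0("t", 2:n_fractions)))
  }

  # onset-time grid: interior observed times (excluding extremes)
  interior <- curve$time_min[curve$time_min > 0 & curve$time_min < tmax]
  t_grid <- if (length(interior)) unique(interior) else tmax / 2

  best <- NULL
  for (t2 in t_grid) {
    onsets <- seq(t2, tmax * 0.9, length.out = n_fractions)[-1]
    if (n_fractions == 2) onsets <- t2
    start <- c(c0 = min(curve$value[1], vmax),
               setNames(rep(vmax / n_fractions, n_fractions), paste0("c", 1:n_fractions)),
               setNames(k_0 * c(1, rep(0.2, n_fractions - 1)), paste0("k", 1:n_fractions)),
               setNames(onsets, paste0("t", 2:n_fractions)))
    fit <- tryCatch(lm_fit(resid_fn, start, lower, upper),
                    error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$rss < best$rss - 1e-12) best <- fit
  }
  if (is.null(best)) {
    fr <- tibble(c_inf = rep(vmax / n_fractions, n_fractions),
                 k = rep(k_0, n_fractions),
                 t_start = c(0, seq_len(n_fractions - 1) * tmax / (2 * n_fractions)))
    return(new_kinetics_fit("CPS", 0, fr, curve, converged = FALSE))
  }
  cf <- best$coef
  fr <- tibble(
    c_inf = unname(cf[paste0("c", 1:n_fractions)]),
    k = unname(cf[paste0("k", 1:n_fractions)]),
    t_start = unname(c(0, cf[paste0("t", 2:n_fractions)]))
  )
  fr <- arrange(fr, .data$t_start)
  fr$t_start[1] <- 0
  new_kinetics_fit("CPS", cf[["c0"]], fr, curve, converged = best$conv)
}

#' Fit digestion kinetics across a digestogram table
#'
#' Applies LOS analysis and model fitting to every
#' sample/protocol/basis/replicate curve in a long digestogram table.
#' Each replicate is fitted independently (so replicate spread can be
#' propagated to predictions); set `pool_replicates = TRUE` to pool a
#' sample's replicate points into one fit instead.
#'
#' @param d Digestogram tibble (see [validate_digestogram()]).
#' @param model `"auto"` (choose SK/CPS per curve by [count_fractions()]),
#'   `"SK"` or `"CPS"`.
#' @param max_fractions Cap on fractions when `model` is `"auto"` or
#'   `"CPS"`.
#' @param pool_replicates Pool replicate points before fitting.
#' @return A tibble with one row per fitted curve: keys, `model`, `c0`,
#'   `c_inf_1`, `k_1`, `t_start_1` (and `_2`, ... when present),
#'   `r_squared`, `rmse`, `converged`, and the fit object in list-column
#'   `fit`.
#' @export
fit_kinetics <- function(d, model = c("auto", "SK", "CPS"),
                         max_fractions = 2, pool_replicates = FALSE) {
  model <- match.arg(model)
  d <- as_tibble(d)
  keys <- c("sample_id", "protocol", "basis",
            if (!pool_replicates) "replicate")
  groups <- distinct(d, across(all_of(keys)))

  purrr::map_dfr(seq_len(nrow(groups)), function(i) {
    g <- groups[i, ]
    sub <- left_join(g, d, by = keys)
    curve <- if (pool_replicates) {
      arrange(sub[, c("time_min", "value")], .data$time_min)
    } else {
      sub[, c("time_min", "value")]
    }
    nf <- 1L
    if (model != "SK") {
      nf <- tryCatch(
        count_fractions(los_transform(curve), max_fractions)$n_fractions,
        error = function(e) 1L)
      if (model == "CPS") nf <- max(nf, 2L)
    }
    fit <- tryCatch(
      if (nf >= 2) fit_cps(curve, nf) else fit_sk(curve),
      error = function(e) NULL)
    if (is.null(fit)) fit <- fit_sk(curve)
    row <- g
    if (pool_replicates) row$replicate <- NA_integer_
    row$model <- fit$model
    row$c0 <- fit$c0
    for (j in seq_len(nrow(fit$fractions))) {
      row[[paste0("c_inf_", j)]] <- fit$fractions$c_inf[j]
      row[[paste0("k_", j)]] <- fit$fractions$k[j]
      row[[paste0("t_start_", j)]] <- fit$fractions$t_start[j]
    }
    row$r_squared <- fit$r_squared
    row$rmse <- fit$rmse
    row$converged <- fit$converged
    row$fit <- list(fit)
    row
  })
}
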