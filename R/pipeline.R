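#' Run the digestion-to-eGI analysis pipeline
#'
#' Orchestrates the full analysis: (optionally) convert raw absorbance
#' readings to digestograms, fit digestion kinetics per replicate,
#' summarize each sample as analytic AUCs, then either *calibrate* a
#' linear GI prediction model against known clinical GI values or
#' *predict* eGI for new samples with a stored model. Validation errors
#' raise; fit non-convergence and over-100% digestibility are collected
#' as warnings in the run log instead.
#'
#' @param digestograms Digestogram tibble or CSV path; alternatively
#'   `NULL` when `absorbance` is given.
#' @param meta Sample metadata tibble or CSV path (clinical GI required in
#'   `"calibrate"` mode; optional in `"predict"` mode, enabling error
#'   rates).
#' @param mode `"calibrate"` or `"predict"`.
#' @param model A `gi_calibration` (object or JSON path); required in
#'   `"predict"` mode.
#' @param absorbance Optional raw absorbance tibble or CSV path, converted
#'   on the requested basis.
#' @param basis Conversion basis when `absorbance` is supplied.
#' @param auc_times AUC horizons in minutes (default 90, 120, 180; the
#'   largest is the calibration predictor).
#' @param kinetics_model Passed to [fit_kinetics()] (`"auto"` default).
#' @param out_dir Optional directory: all stage outputs are written there.
#' @return An object of class `pipeline_run`: list with `digestograms`,
#'   `fits`, `auc`, `aucr` (per-sample mean and SD of the calibration AUC),
#'   `correlations` and `calibration` (calibrate mode), `predictions`
#'   (predict mode), and `log` (character vector of warnings).
#' @export
run_pipeline <- function(digestograms = NULL, meta = NULL,
                         mode = c("calibrate", "predict"),
                         model = NULL, absorbance = NULL,
                         basis = "REDUCING_SUGAR_NORMALIZED",
                         auc_times = c(90, 120, 180),
                         kinetics_model = "auto",
                         out_dir = NULL) {
  mode <- match.arg(mode)
  log <- character()
  note <- function(msg) log <<- c(log, msg)

  if (is.character(meta)) meta <- read_sample_metadata(meta)
  if (!is.null(meta)) meta <- validate_sample_meta(meta)

  if (!is.null(absorbance)) {
    if (is.character(absorbance)) {
      absorbance <- read_digestion_table(absorbance, schema = "absorbance")
    }
    if (is.null(meta)) abort("Converting absorbance requires sample metadata.")
    digestograms <- withCallingHandlers(
      convert_absorbance(absorbance, meta, basis = basis),
      warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })
  } else if (is.character(digestograms)) {
    digestograms <- read_digestion_table(digestograms, schema = "digestogram")
  }
  if (is.null(digestograms) || nrow(as_tibble(digestograms)) == 0) {
    abort("No digestogram input provided.")
  }
  digestograms <- withCallingHandlers(
    validate_digestogram(digestograms),
    warning = function(w) { note(conditionMessage(w)); invokeRestart("muffleWarning") })

  if (mode == "predict" && is.null(model)) {
    abort("predict mode requires a calibration model (object or JSON path).")
  }
  if (is.character(model)) model <- read_calibration(model)

  fits <- withCallingHandlers(
    fit_kinetics(digestograms, model = kinetics_model),
    message = function(m) { note(conditionMessage(m)); invokeRestart("muffleMessage") })
  n_nc <- sum(!fits$converged)
  if (n_nc > 0) note(sprintf("%d kinetics fit(s) did not converge.", n_nc))

  auc <- auc_metrics(fits, horizons = auc_times)
  T_cal <- max(auc_times)
  aucr <- auc %>%
    filter(.data$horizon_T == T_cal) %>%
    group_by(.data$sample_id, .data$protocol, .data$basis) %>%
    summarise(aucr = mean(.data$auc),
              aucr_sd = if (dplyr::n() > 1) sd(.data$auc) else 0,
              .groups = "drop")

  run <- structure(
    list(mode = mode, digestograms = digestograms, fits = fits,
         auc = auc, aucr = aucr, auc_times = auc_times,
         correlations = NULL, calibration = NULL, predictions = NULL,
         log = log),
    class = "pipeline_run"
  )

  if (mode == "calibrate") {
    if (is.null(meta) || !"clinical_gi" %in% names(meta) ||
        anyNA(meta$clinical_gi[meta$sample_id %in% aucr$sample_id])) {
      abort("calibrate mode requires clinical_gi for every sample.")
    }
    cal_df <- left_join(aucr, meta[, intersect(c("sample_id", "clinical_gi",
                                                 "total_carb_pct"), names(meta))],
                        by = "sample_id")
    # feature table: mean kinetics parameters + AUCs per sample
    feats <- fits %>%
      group_by(.data$sample_id) %>%
      summarise(k = mean(.data$k_1), c_inf = mean(.data$c_inf_1), .groups = "drop")
    auc_wide <- auc %>%
      group_by(.data$sample_id, .data$horizon_T) %>%
      summarise(auc = mean(.data$auc), .groups = "drop") %>%
      tidyr::pivot_wider(names_from = "horizon_T", values_from = "auc",
                         names_prefix = "AUC")
    feats <- left_join(feats, auc_wide, by = "sample_id") %>%
      left_join(cal_df[, c("sample_id", "clinical_gi", "total_carb_pct")],
                by = "sample_id")
    gl <- if ("total_carb_pct" %in% names(feats) && !anyNA(feats$total_carb_pct)) {
      glycemic_load(feats$clinical_gi, feats$total_carb_pct)
    } else NULL
    run$correlations <- correlation_screen(
      feats[, setdiff(names(feats), c("clinical_gi", "total_carb_pct"))],
      gi = feats$clinical_gi, gl = gl)
    run$calibration <- fit_calibration(
      cal_df, aucr180 = "aucr", gi = "clinical_gi",
      protocol = first(aucr$protocol), basis = first(aucr$basis))
  } else {
    gi <- NULL
    if (!is.null(meta) && "clinical_gi" %in% names(meta)) {
      gi <- meta$clinical_gi[match(aucr$sample_id, meta$sample_id)]
      if (all(is.na(gi))) gi <- NULL
    }
    run$predictions <- predict_egi(model, aucr$aucr, aucr180_sd = aucr$aucr_sd,
                                   sample_id = aucr$sample_id, clinical_gi = gi)
  }

  run$log <- log
  if (!is.null(out_dir)) render_tables(run, out_dir)
  run
}

#' @export
print.pipeline_run <- function(x, ...) {
  cat("<pipeline_run>", x$mode, "mode:",
      nrow(x$fits), "fitted curve(s),",
      length(unique(x$fits$sample_id)), "sample(s)\n")
  if (!is.null(x$calibration)) print(x$calibration)
  if (!is.null(x$predictions)) print(x$predictions)
  if (length(x$log)) cat("  warnings:", length(x$log), "\n")
  invisible(x)
}

#' Render summary tables from a pipeline run
#'
#' Writes the run's stage outputs as CSV/JSON: the per-curve kinetics fit
#' table, the AUC metrics, and — depending on mode — a starred correlation
#' table plus serialized calibration model, or a prediction report
#' (eGI and SD to 2 dp, error rate when clinical GI is known).
#'
#' @param run A [run_pipeline()] result.
#' @param dir Output directory (created if absent).
#' @return Named character vector of the files written, invisibly.
#' @export
render_tables <- function(run, dir) {
  stopifnot(inherits(run, "pipeline_run"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  files <- c()

  fit_cols <- setdiff(names(run$fits), "fit")
  f <- file.path(dir, "kinetics_fits.csv")
  readr::write_csv(run$fits[, fit_cols], f)
  files["fits"] <- f

  f <- file.path(dir, "auc_metrics.csv")
  readr::write_csv(run$auc, f)
  files["auc"] <- f

  if (!is.null(run$correlations)) {
    f <- file.path(dir, "correlation_table.csv")
    readr::write_csv(run$correlations, f)
    files["correlations"] <- f
  }
  if (!is.null(run$calibration)) {
    f <- file.path(dir, "calibration_model.json")
    write_calibration(run$calibration, f)
    files["calibration"] <- f
  }
  if (!is.null(run$predictions)) {
    pred <- run$predictions %>%
      mutate(egi = round(.data$egi, 2), egi_sd = round(.data$egi_sd, 2))
    f <- file.path(dir, "predictions.csv")
    readr::write_csv(pred, f)
    files["predictions"] <- f
  }
  if (length(run$log)) {
    f <- file.path(dir, "warnings.log")
    writeLines(run$log, f)
    files["log"] <- f
  }
  invisible(files)
}
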