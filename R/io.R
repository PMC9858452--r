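#' Validate a digestogram table
#'
#' A digestogram is a long tibble of digestion extent versus time, one row
#' per (sample, protocol, replicate, timepoint). Within each
#' sample/protocol/replicate/basis group the times must be strictly
#' increasing with at least four points, values non-negative, and
#' percent-starch values at most 110 (assay overshoot above 100 is
#' tolerated with a warning, never clipped).
#'
#' @param d Data frame with columns `sample_id`, `protocol`, `replicate`,
#'   `basis`, `time_min`, `value`.
#' @param min_points Minimum timepoints per curve (default 4).
#' @return The validated tibble, sorted by group and time.
#' @export
validate_digestogram <- function(d, min_points = 4) {
  d <- as_tibble(d)
  need <- c("sample_id", "protocol", "replicate", "basis", "time_min", "value")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    abort(paste0("Digestogram is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (nrow(d) == 0) abort("Digestogram table is empty.")
  bad_proto <- setdiff(unique(d$protocol), PROTOCOLS)
  if (length(bad_proto)) {
    abort(paste0("Unknown protocol(s): ", paste(bad_proto, collapse = ", ")))
  }
  bad_basis <- setdiff(unique(d$basis), BASES)
  if (length(bad_basis)) {
    abort(paste0("Unknown basis value(s): ", paste(bad_basis, collapse = ", ")))
  }
  if (any(!is.finite(d$time_min) | d$time_min < 0)) {
    abort("time_min must be finite and non-negative.")
  }
  if (any(!is.finite(d$value) | d$value < 0)) {
    abort("Digestogram values must be finite and non-negative.")
  }
  over <- d$basis == "PERCENT_STARCH" & d$value > 110
  if (any(over)) {
    abort(sprintf("PERCENT_STARCH values above 110%% at rows %s.",
                  paste(which(over), collapse = ", ")))
  }
  flag <- d$basis == "PERCENT_STARCH" & d$value > 100
  if (any(flag)) {
    warn(sprintf("%d digestogram value(s) exceed 100%% digested (retained, not clipped).",
                 sum(flag)))
  }

  d <- arrange(d, .data$sample_id, .data$protocol, .data$replicate,
               .data$basis, .data$time_min)
  chk <- d %>%
    group_by(.data$sample_id, .data$protocol, .data$replicate, .data$basis) %>%
    summarise(n = dplyr::n(),
              dup = any(diff(.data$time_min) <= 0),
              .groups = "drop")
  if (any(chk$dup)) {
    off <- chk[chk$dup, ]
    abort(paste0("Non-increasing or duplicate timepoints within group(s): ",
                 paste(sprintf("%s/%s/rep%s", off$sample_id, off$protocol,
                               off$replicate), collapse = "; ")))
  }
  if (any(chk$n < min_points)) {
    off <- chk[chk$n < min_points, ]
    abort(paste0("Fewer than ", min_points, " timepoints for group(s): ",
                 paste(sprintf("%s/%s/rep%s", off$sample_id, off$protocol,
                               off$replicate), collapse = "; ")))
  }
  d
}

#' Read a digestion data table from CSV
#'
#' Reads either a digestogram table (`sample_id,protocol,replicate,basis,
#' time_min,value`) or a raw absorbance table (`sample_id,protocol,
#' replicate,time_min,dA_sample,dA_standard[,standard_conc_mmol_per_L,
#' aliquot_volume_uL]`), validates every row against the type invariants,
#' and returns rows grouped by sample/protocol/replicate and sorted by time.
#'
#' @param path CSV file path (UTF-8, header required, `.` decimal).
#' @param schema `"digestogram"` or `"absorbance"`.
#' @return A validated tibble.
#' @export
read_digestion_table <- function(path, schema = c("digestogram", "absorbance")) {
  schema <- match.arg(schema)
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  d <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (schema == "digestogram") {
    return(validate_digestogram(d))
  }
  need <- c("sample_id", "protocol", "replicate", "time_min",
            "dA_sample", "dA_standard")
  missing_cols <- setdiff(need, names(d))
  if (length(missing_cols)) {
    abort(paste0("Absorbance table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (any(!is.finite(d$dA_standard) | d$dA_standard <= 0)) {
    abort("dA_standard must be positive in every row.")
  }
  if (any(!is.finite(d$time_min) | d$time_min < 0)) {
    abort("time_min must be finite and non-negative.")
  }
  if (any(d$dA_sample < 0)) abort("dA_sample must be non-negative.")
  d <- arrange(d, .data$sample_id, .data$protocol, .data$replicate, .data$time_min)
  dup <- d %>%
    group_by(.data$sample_id, .data$protocol, .data$replicate) %>%
    summarise(dup = any(diff(.data$time_min) <= 0), .groups = "drop")
  if (any(dup$dup)) {
    off <- dup[dup$dup, ]
    abort(paste0("Duplicate timepoints within group(s): ",
                 paste(sprintf("%s/%s/rep%s", off$sample_id, off$protocol,
                               off$replicate), collapse = "; ")))
  }
  d
}

#' Write a digestion table to CSV
#'
#' Full-precision CSV output; a table written and re-read with
#' [read_digestion_table()] reproduces identical values.
#'
#' @param d Digestogram (or absorbance) tibble.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_digestion_table <- function(d, path) {
  readr::write_csv(as_tibble(d), path)
  invisible(path)
}

#' Read sample metadata from CSV
#'
#' @param path CSV with columns `sample_id,clinical_gi,total_carb_pct,
#'   total_starch_pct_db,protein_pct,fat_pct,moisture_pct,free_sugar_pct,
#'   sample_mass_mg` (optional fields may be empty).
#' @return Validated metadata tibble.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  validate_sample_meta(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

#' Extract one digestion curve from a digestogram table
#'
#' Convenience selector returning the (time, value) series for a single
#' sample/protocol/replicate/basis combination.
#'
#' @param d Digestogram tibble.
#' @param sample_id,protocol,replicate,basis Group keys; `NULL` matches all,
#'   but the result must be a single curve.
#' @return Tibble with `time_min`, `value`, sorted by time.
#' @export
digestogram_curve <- function(d, sample_id = NULL, protocol = NULL,
                              replicate = NULL, basis = NULL) {
  d <- as_tibble(d)
  if (!is.null(sample_id)) d <- d[d$sample_id %in% sample_id, ]
  if (!is.null(protocol)) d <- d[d$protocol %in% protocol, ]
  if (!is.null(replicate)) d <- d[d$replicate %in% replicate, ]
  if (!is.null(basis)) d <- d[d$basis %in% basis, ]
  keys <- distinct(d, .data$sample_id, .data$protocol, .data$replicate, .data$basis)
  if (nrow(keys) != 1) {
    abort(sprintf("Selection matches %d curves; expected exactly 1.", nrow(keys)))
  }
  arrange(d, .data$time_min)[, c("time_min", "value")]
}
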