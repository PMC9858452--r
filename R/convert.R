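#' Conversion constants for the reducing-sugar assay
#'
#' Constants of the colorimetric (PAHBAH, maltose-standard) assay chain that
#' turns an absorbance difference into a digested-starch mass. The maltose
#' molecular weight is 342 mg/mmol; one maltose is two anhydroglucose units
#' (2 x 162 = 324), so 324/342 converts maltose mass to starch-equivalent
#' mass. The dilution factor scales the assayed aliquot back up to the
#' digestion vessel.
#'
#' The default dilution factors reproduce the published computational
#' multiples for each protocol (50 x 50 = 2500 for INFOGEST, 5 x 150 = 750
#' for the single-enzyme protocols). These printed multiples are not
#' consistent with the stated vessel volumes (50 mL and 18 mL against a
#' 0.2 mL aliquot give 250 and 90); a warning is emitted when a supplied
#' `vessel_volume_mL` disagrees with the factor in use. Override
#' `dilution_factor` to use volume-derived values instead.
#'
#' @param protocol One of `"INFOGEST"`, `"PANCREATIN"`, `"AMYLASE"`.
#' @param dilution_factor Dimensionless aliquot-to-vessel multiple; defaults
#'   to the printed protocol value (2500 or 750).
#' @param vessel_volume_mL Optional vessel volume for a consistency check
#'   against `dilution_factor` (assuming the 0.2 mL quenched aliquot).
#' @return A list of class `conversion_constants` with fields `maltose_mw`
#'   (342 mg/mmol), `starch_to_maltose_weight_ratio` (324/342),
#'   `dilution_factor`, `protocol`.
#' @examples
#' conversion_constants("PANCREATIN")
#' @export
conversion_constants <- function(protocol = c("INFOGEST", "PANCREATIN", "AMYLASE"),
                                 dilution_factor = NULL,
                                 vessel_volume_mL = NULL) {
  protocol <- match.arg(protocol)
  if (is.null(dilution_factor)) {
    dilution_factor <- if (protocol == "INFOGEST") 50 * 50 else 5 * 150
  }
  if (!is.numeric(dilution_factor) || length(dilution_factor) != 1 ||
      !is.finite(dilution_factor) || dilution_factor <= 0) {
    abort("`dilution_factor` must be a single positive number.")
  }
  if (!is.null(vessel_volume_mL)) {
    implied <- vessel_volume_mL / 0.2
    if (abs(implied - dilution_factor) / dilution_factor > 1e-6) {
      warn(sprintf(paste0(
        "dilution_factor %g disagrees with the vessel-volume-derived value ",
        "%g (= %g mL / 0.2 mL aliquot); the configured factor is used."),
        dilution_factor, implied, vessel_volume_mL))
    }
  }
  structure(
    list(
      maltose_mw = 342,
      starch_to_maltose_weight_ratio = 324 / 342,
      dilution_factor = dilution_factor,
      protocol = protocol
    ),
    class = "conversion_constants"
  )
}

#' @export
print.conversion_constants <- function(x, ...) {
  cat("<conversion_constants>", x$protocol,
      "| dilution", x$dilution_factor,
      "| maltose MW", x$maltose_mw, "mg/mmol",
      "| starch/maltose", signif(x$starch_to_maltose_weight_ratio, 6), "\n")
  invisible(x)
}

#' Validate sample metadata
#'
#' Checks a metadata table (one row per sample: clinical GI where known,
#' proximate composition, and the sample mass loaded into the digestion
#' vessel) against its invariants and returns it as a tibble.
#'
#' @param meta Data frame with columns `sample_id`, `sample_mass_mg`,
#'   and any of `clinical_gi`, `total_carb_pct`, `total_starch_pct_db`,
#'   `protein_pct`, `fat_pct`, `moisture_pct`, `free_sugar_pct`.
#' @return The validated tibble.
#' @export
validate_sample_meta <- function(meta) {
  meta <- as_tibble(meta)
  need <- c("sample_id", "sample_mass_mg")
  missing_cols <- setdiff(need, names(meta))
  if (length(missing_cols)) {
    abort(paste0("Metadata is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(meta$sample_id)) {
    abort("Metadata has duplicated sample_id values.")
  }
  if (any(!is.finite(meta$sample_mass_mg) | meta$sample_mass_mg <= 0)) {
    abort("sample_mass_mg must be positive.")
  }
  pct_cols <- intersect(
    c("total_carb_pct", "total_starch_pct_db", "protein_pct", "fat_pct",
      "moisture_pct", "free_sugar_pct"), names(meta))
  for (cl in pct_cols) {
    v <- meta[[cl]]
    bad <- !is.na(v) & (v < 0 | v > 100)
    if (any(bad)) {
      abort(sprintf("Column %s has values outside [0, 100] (rows %s).",
                    cl, paste(which(bad), collapse = ", ")))
    }
  }
  if ("clinical_gi" %in% names(meta)) {
    v <- meta$clinical_gi
    if (any(!is.na(v) & v <= 0)) abort("clinical_gi must be positive when present.")
  }
  meta
}

# Maltose mass (mg) released in the whole vessel implied by one absorbance
# reading: the shared head of both conversion chains.
maltose_mass_mg <- function(dA_sample, dA_standard, standard_conc_mmol_per_L,
                            aliquot_volume_uL, consts) {
  if (any(!is.finite(dA_standard) | dA_standard <= 0)) {
    abort("dA_standard must be positive.")
  }
  if (any(dA_sample < 0)) abort("dA_sample must be non-negative.")
  conc <- dA_sample / dA_standard * standard_conc_mmol_per_L   # mmol/L
  mmol <- conc * aliquot_volume_uL * 1e-6                      # L -> mmol
  mmol * consts$maltose_mw * consts$dilution_factor            # mg in vessel
}

#' Convert an absorbance reading to percent starch digested
#'
#' Implements the assay arithmetic: the sample/standard absorbance ratio
#' gives a maltose concentration, which over the assayed aliquot volume and
#' vessel dilution gives the maltose mass released in the vessel; the
#' 324/342 weight ratio converts that to starch-equivalent mass, expressed
#' as a percentage of the starch loaded
#' (`sample_mass_mg * total_starch_pct_db / 100`).
#'
#' @param dA_sample Absorbance difference of the sample (>= 0).
#' @param dA_standard Absorbance difference of the maltose standard,
#'   per `standard_conc_mmol_per_L` (> 0).
#' @param sample_mass_mg Sample mass in the vessel (mg).
#' @param total_starch_pct_db Total starch, percent dry basis.
#' @param consts A [conversion_constants()] object.
#' @param standard_conc_mmol_per_L Concentration of the maltose standard
#'   (default 1 mmol/L).
#' @param aliquot_volume_uL Volume of supernatant assayed (default 100).
#' @return Percent starch digested (vectorized over readings).
#' @examples
#' consts <- conversion_constants("INFOGEST")
#' absorbance_to_percent_digested(0.4, 0.8, sample_mass_mg = 5000,
#'   total_starch_pct_db = 10, consts = consts)
#' @export
absorbance_to_percent_digested <- function(dA_sample, dA_standard,
                                           sample_mass_mg, total_starch_pct_db,
                                           consts = conversion_constants(),
                                           standard_conc_mmol_per_L = 1,
                                           aliquot_volume_uL = 100) {
  starch_mg <- sample_mass_mg * total_starch_pct_db / 100
  if (any(!is.finite(starch_mg) | starch_mg <= 0)) {
    abort(paste0("Starch mass (sample_mass_mg * total_starch_pct_db / 100) ",
                 "must be positive; for starch-free samples use the ",
                 "REDUCING_SUGAR_NORMALIZED basis instead."))
  }
  maltose <- maltose_mass_mg(dA_sample, dA_standard, standard_conc_mmol_per_L,
                             aliquot_volume_uL, consts)
  maltose * consts$starch_to_maltose_weight_ratio / starch_mg * 100
}

#' Convert an absorbance reading to carbohydrate-normalized reducing sugar
#'
#' Same maltose-mass chain as [absorbance_to_percent_digested()], but the
#' released reducing sugar is left as maltose mass (no 324/342 starch
#' conversion) and normalized to the total available carbohydrate mass
#' (`sample_mass_mg * total_carb_pct / 100`), times 100.
#'
#' @inheritParams absorbance_to_percent_digested
#' @param total_carb_pct Total carbohydrates, percent of sample mass.
#' @return Normalized reducing-sugar value (dimensionless x 100).
#' @export
absorbance_to_normalized_reducing_sugar <- function(dA_sample, dA_standard,
                                                    sample_mass_mg, total_carb_pct,
                                                    consts = conversion_constants(),
                                                    standard_conc_mmol_per_L = 1,
                                                    aliquot_volume_uL = 100) {
  carb_mg <- sample_mass_mg * total_carb_pct / 100
  if (any(!is.finite(carb_mg) | carb_mg <= 0)) {
    abort("Total carbohydrate mass must be positive.")
  }
  maltose <- maltose_mass_mg(dA_sample, dA_standard, standard_conc_mmol_per_L,
                             aliquot_volume_uL, consts)
  maltose / carb_mg * 100
}

#' Convert a table of absorbance readings into digestograms
#'
#' Data-frame-first wrapper around the two conversion chains: joins each
#' absorbance record to its sample metadata, applies the protocol's
#' conversion constants, and returns a long digestogram table.
#'
#' @param data Absorbance table with columns `sample_id`, `protocol`,
#'   `replicate`, `time_min`, `dA_sample`, `dA_standard`, and optionally
#'   `standard_conc_mmol_per_L` (default 1) and `aliquot_volume_uL`
#'   (default 100).
#' @param meta Sample metadata (see [validate_sample_meta()]).
#' @param basis `"PERCENT_STARCH"` or `"REDUCING_SUGAR_NORMALIZED"`.
#' @param constants Optional named list of [conversion_constants()] per
#'   protocol; defaults are built per protocol present in `data`.
#' @return A digestogram tibble with columns `sample_id`, `protocol`,
#'   `replicate`, `basis`, `time_min`, `value`. Percent-starch values above
#'   100 are retained (never clipped) and trigger a warning; values above
#'   110 are rejected.
#' @export
convert_absorbance <- function(data, meta,
                               basis = c("PERCENT_STARCH", "REDUCING_SUGAR_NORMALIZED"),
                               constants = NULL) {
  basis <- match.arg(basis)
  data <- as_tibble(data)
  meta <- validate_sample_meta(meta)
  need <- c("sample_id", "protocol", "replicate", "time_min",
            "dA_sample", "dA_standard")
  missing_cols <- setdiff(need, names(data))
  if (length(missing_cols)) {
    abort(paste0("Absorbance table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  if (!"standard_conc_mmol_per_L" %in% names(data)) data$standard_conc_mmol_per_L <- 1
  if (!"aliquot_volume_uL" %in% names(data)) data$aliquot_volume_uL <- 100
  unknown <- setdiff(unique(data$sample_id), meta$sample_id)
  if (length(unknown)) {
    abort(paste0("No metadata for sample(s): ", paste(unknown, collapse = ", ")))
  }
  bad_proto <- setdiff(unique(data$protocol), PROTOCOLS)
  if (length(bad_proto)) {
    abort(paste0("Unknown protocol(s): ", paste(bad_proto, collapse = ", ")))
  }

  meta_cols <- intersect(c("sample_id", "sample_mass_mg", "total_starch_pct_db",
                           "total_carb_pct"), names(meta))
  joined <- left_join(data, meta[meta_cols], by = "sample_id")

  out <- joined %>%
    group_by(.data$protocol) %>%
    mutate(value = {
      cst <- if (!is.null(constants)) constants[[first(.data$protocol)]] else
        conversion_constants(first(.data$protocol))
      if (basis == "PERCENT_STARCH") {
        absorbance_to_percent_digested(
          .data$dA_sample, .data$dA_standard,
          .data$sample_mass_mg, .data$total_starch_pct_db, cst,
          .data$standard_conc_mmol_per_L, .data$aliquot_volume_uL)
      } else {
        absorbance_to_normalized_reducing_sugar(
          .data$dA_sample, .data$dA_standard,
          .data$sample_mass_mg, .data$total_carb_pct, cst,
          .data$standard_conc_mmol_per_L, .data$aliquot_volume_uL)
      }
    }) %>%
    ungroup() %>%
    mutate(basis = basis) %>%
    select(all_of(c("sample_id", "protocol", "replicate", "basis",
                    "time_min", "value"))) %>%
    arrange(.data$sample_id, .data$protocol, .data$replicate, .data$time_min)
  validate_digestogram(out)
}

#' Glycemic load from GI and carbohydrate content
#'
#' GL = GI x carbohydrate content (fraction of sample mass), reported to
#' two decimals as in food-composition tables.
#'
#' @param gi Glycemic index (>= 0), vectorized.
#' @param carb_pct Total carbohydrate content, percent in `[0, 100]`.
#' @return Glycemic load, rounded to 2 decimals.
#' @examples
#' glycemic_load(9, 14.15)   # 1.27
#' glycemic_load(30, 15.86)  # 4.76
#' @export
glycemic_load <- function(gi, carb_pct) {
  if (any(gi < 0, na.rm = TRUE)) abort("gi must be non-negative.")
  if (any(carb_pct < 0 | carb_pct > 100, na.rm = TRUE)) {
    abort("carb_pct must lie in [0, 100].")
  }
  round(gi * carb_pct / 100, 2)
}
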