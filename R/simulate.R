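#' Simulate first-order digestograms
#'
#' Evaluates the SK/CPS forward model
#' `C(t) = C0 + sum_j Cinf_j (1 - e^{-k_j (t - t_jstart)}) 1[t > t_jstart]`
#' at the schedule times, adds i.i.d. Gaussian noise and truncates at zero
#' — emulating duplicate reducing-sugar assay measurements on either the
#' INFOGEST intestinal (0--120 min) or single-enzyme (5--240 min) sampling
#' schedule. Deterministic given `seed`.
#'
#' @param fractions Tibble/data frame with `c_inf`, `k` (1/min) and
#'   `t_start` (min; first must be 0) — one row per digestible fraction.
#' @param c0 Digested amount at t = 0 (default 0).
#' @param schedule `"SINGLE_ENZYME"`, `"INFOGEST_INTESTINAL"`, or an
#'   explicit numeric vector of minutes.
#' @param noise_sd SD of additive Gaussian assay noise (value units).
#' @param n_replicates Number of replicate series (default 2, duplicate
#'   assays).
#' @param sample_id,protocol,basis Identity columns of the output.
#' @param seed Optional RNG seed for reproducibility.
#' @return A digestogram tibble (`sample_id`, `protocol`, `replicate`,
#'   `basis`, `time_min`, `value`).
#' @examples
#' simulate_digestogram(tibble::tibble(c_inf = 40, k = 0.03, t_start = 0),
#'                      noise_sd = 0, n_replicates = 1)
#' @export
simulate_digestogram <- function(fractions, c0 = 0,
                                 schedule = "SINGLE_ENZYME",
                                 noise_sd = 0.3, n_replicates = 2,
                                 sample_id = "S1", protocol = "PANCREATIN",
                                 basis = "REDUCING_SUGAR_NORMALIZED",
                                 seed = NULL) {
  fractions <- as_tibble(fractions)
  stopifnot(all(c("c_inf", "k") %in% names(fractions)))
  if (!"t_start" %in% names(fractions)) fractions$t_start <- 0
  if (any(fractions$k <= 0)) abort("All k must be positive.")
  if (noise_sd < 0) abort("noise_sd must be non-negative.")
  times <- if (is.character(schedule)) digestion_schedule(schedule) else as.numeric(schedule)
  if (any(diff(times) <= 0)) abort("Schedule times must be strictly increasing.")
  if (!is.null(seed)) set.seed(seed)

  truth <- kinetics_curve(c0, fractions, times)
  purrr::map_dfr(seq_len(n_replicates), function(r) {
    v <- truth + if (noise_sd > 0) rnorm(length(times), 0, noise_sd) else 0
    tibble(sample_id = sample_id, protocol = protocol, replicate = r,
           basis = basis, time_min = times, value = pmax(v, 0))
  })
}

#' Simulate raw absorbance series for a digestogram
#'
#' Inverts the reducing-sugar conversion chain so that running the
#' resulting absorbance records through [convert_absorbance()] reproduces
#' the digestogram exactly (to rounding noise of the inversion, < 1e-9).
#' Useful for exercising the raw-assay ingestion path with known truth.
#'
#' @param d A digestogram tibble (a single basis).
#' @param meta Sample metadata (see [validate_sample_meta()]).
#' @param consts A [conversion_constants()] object matching the protocol;
#'   built per protocol when `NULL`.
#' @param dA_standard Absorbance of the 1 mmol/L maltose standard
#'   (default 0.8).
#' @param aliquot_volume_uL Assayed aliquot volume (default 100).
#' @return An absorbance tibble accepted by [convert_absorbance()] and
#'   [read_digestion_table()] (`schema = "absorbance"`).
#' @export
simulate_absorbance_series <- function(d, meta, consts = NULL,
                                       dA_standard = 0.8,
                                       aliquot_volume_uL = 100) {
  d <- as_tibble(d)
  meta <- validate_sample_meta(meta)
  basis_kind <- unique(d$basis)
  if (length(basis_kind) != 1) abort("Digestogram must have a single basis.")
  joined <- left_join(
    d, meta[intersect(c("sample_id", "sample_mass_mg", "total_starch_pct_db",
                        "total_carb_pct"), names(meta))],
    by = "sample_id")

  joined %>%
    group_by(.data$protocol) %>%
    mutate(dA_sample = {
      cst <- consts %||% conversion_constants(first(.data$protocol))
      norm_mg <- if (basis_kind == "PERCENT_STARCH") {
        .data$sample_mass_mg * .data$total_starch_pct_db / 100
      } else {
        .data$sample_mass_mg * .data$total_carb_pct / 100
      }
      ratio <- if (basis_kind == "PERCENT_STARCH") cst$starch_to_maltose_weight_ratio else 1
      maltose_mg <- .data$value / 100 * norm_mg / ratio
      mmol <- maltose_mg / (cst$maltose_mw * cst$dilution_factor)
      conc <- mmol / (aliquot_volume_uL * 1e-6)
      conc / 1 * dA_standard
    }) %>%
    ungroup() %>%
    mutate(dA_standard = dA_standard,
           standard_conc_mmol_per_L = 1,
           aliquot_volume_uL = aliquot_volume_uL) %>%
    select(all_of(c("sample_id", "protocol", "replicate", "time_min",
                    "dA_sample", "dA_standard", "standard_conc_mmol_per_L",
                    "aliquot_volume_uL")))
}

#' Simulate a full GI calibration study
#'
#' Generates a set of samples whose 180-min reducing-sugar AUC (AUCR180)
#' targets are drawn uniformly in `aucr_range`, whose clinical GI follows
#' the linear law `GI = intercept + slope * AUCR180` plus Gaussian noise,
#' and whose digestograms are single-fraction first-order curves whose
#' analytic 180-min AUC equals the target exactly: `C0` is fixed at 0, a
#' rate `k` is drawn uniformly in `[0.005, 0.05]` 1/min, and the plateau
#' solves `Cinf = AUCR / (180 - (1 - e^{-180 k}) / k)` (resampled if
#' non-positive). Feeding the result through the fitting and calibration
#' pipeline should recover `(intercept, slope)` — the closed loop used to
#' validate the whole method.
#'
#' @param n_samples Number of calibration samples (default 8).
#' @param intercept,slope True calibration line (defaults 1.834 and 0.009,
#'   a realistic pancreatin-protocol line for low-GI biscuits).
#' @param aucr_range Range of AUCR180 targets (default 500--3500).
#' @param gi_noise_sd SD of GI noise around the line (default 1).
#' @param digestogram_noise_sd Assay noise SD on digestogram values
#'   (default 0.3).
#' @param n_replicates Replicate digestograms per sample (default 2).
#' @param schedule Sampling schedule (default `"SINGLE_ENZYME"`).
#' @param protocol,basis Labels for the generated digestograms.
#' @param seed Optional RNG seed.
#' @return A list with `meta` (tibble: `sample_id`, `clinical_gi`, and
#'   plumbing columns for conversion), `digestograms` (long tibble), and
#'   `truth` (tibble of generating parameters per sample: `aucr180_target`,
#'   `c0`, `c_inf`, `k`, `gi_true_line`, `clinical_gi`).
#' @export
simulate_calibration_study <- function(n_samples = 8, intercept = 1.834,
                                       slope = 0.009,
                                       aucr_range = c(500, 3500),
                                       gi_noise_sd = 1,
                                       digestogram_noise_sd = 0.3,
                                       n_replicates = 2,
                                       schedule = "SINGLE_ENZYME",
                                       protocol = "PANCREATIN",
                                       basis = "REDUCING_SUGAR_NORMALIZED",
                                       seed = NULL) {
  if (n_samples < 4) abort("n_samples must be at least 4.")
  if (aucr_range[1] >= aucr_range[2]) abort("aucr_range must be (lo, hi) with lo < hi.")
  if (slope == 0) abort("slope must be nonzero.")
  if (!is.null(seed)) set.seed(seed)
  T_cal <- 180

  ids <- sprintf("SYN%02d", seq_len(n_samples))
  targets <- runif(n_samples, aucr_range[1], aucr_range[2])
  solve_cinf <- function(target) {
    for (try in 1:20) {
      k <- runif(1, 0.005, 0.05)
      cinf <- target / (T_cal - (1 - exp(-k * T_cal)) / k)
      if (is.finite(cinf) && cinf > 0) return(c(k = k, c_inf = cinf))
    }
    abort("Could not solve a positive Cinf for an AUCR target.")
  }
  pars <- t(vapply(targets, solve_cinf, numeric(2)))
  gi_line <- intercept + slope * targets
  gi <- gi_line + if (gi_noise_sd > 0) rnorm(n_samples, 0, gi_noise_sd) else 0

  truth <- tibble(
    sample_id = ids, aucr180_target = targets, c0 = 0,
    c_inf = pars[, "c_inf"], k = pars[, "k"],
    gi_true_line = gi_line, clinical_gi = gi
  )
  digestograms <- purrr::map_dfr(seq_len(n_samples), function(i) {
    simulate_digestogram(
      tibble(c_inf = truth$c_inf[i], k = truth$k[i], t_start = 0),
      c0 = 0, schedule = schedule, noise_sd = digestogram_noise_sd,
      n_replicates = n_replicates, sample_id = ids[i],
      protocol = protocol, basis = basis)
  })
  meta <- tibble(
    sample_id = ids, clinical_gi = gi,
    total_carb_pct = 20, total_starch_pct_db = 10, sample_mass_mg = 300
  )
  list(meta = meta, digestograms = digestograms, truth = truth)
}

#' Write a simulated study to disk
#'
#' Emits the tabular interchange files of a simulated calibration study:
#' `digestograms.csv`, `absorbance.csv`, `metadata.csv` and a ground-truth
#' `truth.json` holding every generating parameter.
#'
#' @param study Output of [simulate_calibration_study()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_simulation <- function(study, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_digestion_table(study$digestograms, file.path(dir, "digestograms.csv"))
  abs <- simulate_absorbance_series(study$digestograms, study$meta)
  write_digestion_table(abs, file.path(dir, "absorbance.csv"))
  readr::write_csv(study$meta, file.path(dir, "metadata.csv"))
  jsonlite::write_json(study$truth, file.path(dir, "truth.json"),
                       auto_unbox = FALSE, digits = NA, pretty = TRUE)
  invisible(dir)
}
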