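#' Analyse one administration session end to end
#'
#' Runs the full pipeline: preprocessing (anchor, window, smooth), metric
#' extraction, classification, and -- when quantification inputs are supplied
#' and the session is classified as extravasation -- residual-activity
#' estimation, self-dose and SUV correction coefficient.
#'
#' @param session An [injection_session()].
#' @param cfg A [preprocess_config()].
#' @param rule A [classification_rule()].
#' @param quantification Optional named list describing the imaging
#'   quantification inputs: either
#'   `list(source = "pet_voi", voi_volume, mean_concentration, elapsed)` or
#'   `list(source = "spect_counts", counts_rate, calibration_factor,
#'   elapsed)`.
#' @param dose_factor_table Optional sphere-model table (see
#'   [dose_factor_lookup()]); with it and a quantified volume the self-dose is
#'   estimated using a soft-tissue density of 1 g/cm^3 for the VOI mass.
#' @param activity_ref Reference activity for the normalised metrics, MBq.
#' @return A `session_report` list: `metrics` (classified one-row tibble),
#'   `quantification` (tibble or `NULL`), `provenance`.
#' @export
analyze_session <- function(session, cfg = preprocess_config(session$modality),
                            rule = classification_rule(),
                            quantification = NULL, dose_factor_table = NULL,
                            activity_ref = 100) {
  metrics <- compute_metrics(session, cfg, activity_ref = activity_ref)
  classified <- classify_session(metrics, rule)
  quant <- NULL
  if (!is.null(quantification)) {
    quant <- .quantify(session, classified$label, quantification, dose_factor_table)
  }
  structure(list(
    metrics = classified,
    quantification = quant,
    provenance = list(
      package_version = as.character(utils::packageVersion("radextra")),
      config = unclass(cfg),
      rule = unclass(rule),
      activity_ref = activity_ref,
      session_id = session$session_id
    )
  ), class = "session_report")
}

.quantify <- function(session, label, q, dose_factor_table) {
  src <- match.arg(q$source, c("pet_voi", "spect_counts"))
  res <- if (src == "pet_voi") {
    residual_from_pet(q$voi_volume, q$mean_concentration,
                      elapsed = q$elapsed %||% 60, nuclide = session$nuclide)
  } else {
    residual_from_spect(q$counts_rate, q$calibration_factor,
                        elapsed = q$elapsed %||% 0, nuclide = session$nuclide)
  }
  suv <- suv_correction(session$A_inj, res$A_rs, label)
  out <- dplyr::bind_cols(res, suv)
  df <- q$dose_factor
  if (is.null(df) && !is.null(dose_factor_table) && !is.null(q$voi_volume)) {
    df <- dose_factor_lookup(q$voi_volume, dose_factor_table)$dose_factor_mGy_MBq
  }
  if (!is.null(df)) {
    out$dose_factor_mGy_MBq <- df
    out$self_dose_mGy <- self_dose(out$A_rs, df)
  }
  out
}

#' @export
print.session_report <- function(x, ...) {
  m <- x$metrics
  cat(sprintf("<session_report> %s (%s): %s%s\n", m$session_id, m$mode,
              m$label,
              if (m$label == "extravasation") paste0(" [", m$triggered_by, "]") else ""))
  cat(sprintf("  delta_p_nor = %.3g, delta_R_t = %.3g uSv/h, t* = %.0f s\n",
              m$delta_p_nor, m$delta_R_t, m$t_star))
  if (!is.null(x$quantification)) {
    q <- x$quantification
    cat(sprintf("  A_rs = %.3g MBq, SUV coeff = %.4g%s\n", q$A_rs, q$SUV_corr_coeff,
                if (!is.null(q$self_dose_mGy)) sprintf(", self-dose = %.3g mGy", q$self_dose_mGy) else ""))
  }
  invisible(x)
}

#' Cohort-level analysis of a labelled metric table
#'
#' Runs the cohort workflow on a labelled table (as produced by
#' [simulate_cohort()] or assembled from per-session reports): class
#' comparison of each metric, the covariate screen, logistic threshold
#' refits, and optionally the SUV calibration.
#'
#' @param table Data frame with a `label` column and metric columns.
#' @param metrics Metric columns to compare/refit.
#' @param covariates Covariate columns for the screen (skipped if absent).
#' @param calibration Optional `c(metric, coefficient)` column-name pair to
#'   fit the SUV calibration on.
#' @return A list: `comparisons`, `thresholds` (named list of
#'   `threshold_fit`s), `covariates`, `calibration`.
#' @export
analyze_cohort <- function(table,
                           metrics = intersect(c("delta_p_nor", "delta_R_t"), names(table)),
                           covariates = intersect(c("age", "weight", "height", "glucose",
                                                    "corticosteroid", "chemotherapy"),
                                                  names(table)),
                           calibration = NULL) {
  stopifnot(is.data.frame(table))
  if (nrow(table) == 0L) {
    abort("The cohort table is empty.", class = "radextra_data_error")
  }
  if (!"label" %in% names(table)) {
    abort("The cohort table needs a `label` column.", class = "radextra_config_error")
  }
  if (length(unique(table$label)) < 2L) {
    abort("Both classes are required for a cohort analysis.",
          class = "radextra_data_error")
  }
  comparisons <- purrr::map(setNames(metrics, metrics), function(m) {
    compare_classes(table, !!rlang::sym(m), .data$label)
  })
  thresholds <- purrr::map(setNames(metrics, metrics), function(m) {
    fit_threshold(table, !!rlang::sym(m), .data$label)
  })
  cov_screen <- if (length(covariates) > 0L) {
    covariate_screen(table, metrics, covariates)
  }
  calib <- if (!is.null(calibration)) {
    fit_suv_calibration(table, !!rlang::sym(calibration[[1L]]),
                        !!rlang::sym(calibration[[2L]]))
  }
  list(comparisons = comparisons, thresholds = thresholds,
       covariates = cov_screen, calibration = calib)
}

#' Write a session report to JSON (and optionally CSV)
#'
#' @param report A `session_report` from [analyze_session()].
#' @param path Output JSON path.
#' @param csv Optional path for a flat one-row CSV of the metrics.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path, csv = NULL) {
  stopifnot(inherits(report, "session_report"))
  jsonlite::write_json(list(
    metrics = report$metrics,
    quantification = report$quantification,
    provenance = report$provenance
  ), path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  if (!is.null(csv)) {
    readr::write_csv(report$metrics, csv, progress = FALSE)
  }
  invisible(path)
}

#' Read a session from a YAML config
#'
#' The config names the curve files and the administration metadata:
#' ```yaml
#' session_id: patient_001
#' modality: diagnostic
#' nuclide: F18
#' A_inj_MBq: 187
#' curves:
#'   injection: injection.csv
#'   contralateral: contralateral.csv   # optional
#' injection_start: 90                  # optional anchor override, s
#' ```
#' Relative curve paths are resolved against the config file's directory.
#'
#' @param path Path to the YAML config.
#' @return An [injection_session()].
#' @export
read_session_config <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("Config not found: %s", path), class = "radextra_format_error")
  }
  cfg <- yaml::read_yaml(path)
  need <- c("modality", "nuclide", "A_inj_MBq", "curves")
  miss <- setdiff(need, names(cfg))
  if (length(miss) > 0L) {
    abort(paste0("Config is missing fields: ", paste(miss, collapse = ", ")),
          class = "radextra_config_error")
  }
  resolve <- function(p) if (file.exists(p)) p else file.path(dirname(path), p)
  inj <- read_dose_curve(resolve(cfg$curves$injection), arm = "injection")
  con <- if (!is.null(cfg$curves$contralateral)) {
    read_dose_curve(resolve(cfg$curves$contralateral), arm = "contralateral")
  }
  injection_session(inj, con, A_inj = cfg$A_inj_MBq, nuclide = cfg$nuclide,
                    modality = cfg$modality,
                    injection_start = cfg$injection_start,
                    session_id = cfg$session_id %||% basename(dirname(path)))
}

#' Write a session (curves + config) to a directory
#'
#' Emits the curve CSVs through the same writer the reader accepts plus a
#' YAML config, so a simulated session can be re-analysed from files exactly
#' like a real acquisition.
#'
#' @param session An [injection_session()].
#' @param dir Output directory (created if needed).
#' @param truth Optional ground-truth list written as `truth.json`.
#' @return The config path, invisibly.
#' @export
write_session <- function(session, dir, truth = NULL) {
  stopifnot(inherits(session, "injection_session"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_dose_curve(session$injection, file.path(dir, "injection.csv"))
  curves <- list(injection = "injection.csv")
  if (!is.null(session$contralateral)) {
    write_dose_curve(session$contralateral, file.path(dir, "contralateral.csv"))
    curves$contralateral <- "contralateral.csv"
  }
  cfg <- list(session_id = session$session_id, modality = session$modality,
              nuclide = session$nuclide, A_inj_MBq = session$A_inj,
              curves = curves)
  if (!is.null(session$injection_start)) cfg$injection_start <- session$injection_start
  cfg_path <- file.path(dir, "session.yaml")
  yaml::write_yaml(cfg, cfg_path)
  if (!is.null(truth)) {
    tr <- truth
    tr$metrics_noise_free <- as.list(tr$metrics_noise_free)
    jsonlite::write_json(tr, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
  }
  invisible(cfg_path)
}

#' Bundled worked-example dosimetry records
#'
#' Two small plain-text tables of severe extravasation cases observed during
#' monitored administrations: `"diagnostic"` (12 PET cases with VOI volume,
#' mean activity concentration, decay-corrected residual activity, sphere
#' dose factor, self-dose and the two curve metrics; `reinjected` marks the
#' patients who required a second injection) and `"therapy"` (one Lu-177
#' radioligand case with SPECT counts). They drive the worked examples and
#' the package's validation suite.
#'
#' @param which `"diagnostic"` or `"therapy"`.
#' @return A tibble.
#' @examples
#' dosimetry_cases("diagnostic")
#' @export
dosimetry_cases <- function(which = c("diagnostic", "therapy")) {
  which <- match.arg(which)
  f <- system.file("extdata",
                   paste0(which, "_dosimetry_cases.csv"),
                   package = "radextra", mustWork = TRUE)
  readr::read_csv(f, show_col_types = FALSE, progress = FALSE)
}
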