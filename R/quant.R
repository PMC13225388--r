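#' Back-correct an activity for physical decay
#'
#' Imaging happens some time after the injection, so the activity measured in
#' the extravasation region is scaled back to injection time with the
#' nuclide's physical half-life: A0 = A * 2^(elapsed / T_half). Only physical
#' decay is considered; biological clearance at the injection site is
#' deliberately ignored (a cautious choice in the absence of patient-specific
#' kinetics).
#'
#' @param activity Activity at measurement time, MBq (vectorised).
#' @param elapsed Minutes between injection and measurement (>= 0).
#' @param nuclide `"F18"`, `"Ga68"` or `"Lu177"`.
#' @return Activity at injection time, MBq.
#' @examples
#' decay_correct(1, 109.77, "F18")  # one half-life -> 2 MBq
#' @export
decay_correct <- function(activity, elapsed, nuclide) {
  if (any(!is.finite(activity)) || any(activity < 0)) {
    abort("`activity` must be non-negative.", class = "radextra_data_error")
  }
  if (any(!is.finite(elapsed)) || any(elapsed < 0)) {
    abort("`elapsed` must be non-negative minutes.", class = "radextra_data_error")
  }
  activity * 2^(elapsed / nuclide_half_life(nuclide))
}

#' Residual activity from PET VOI statistics
#'
#' The extravasation region is segmented on the PET image at 10% of the
#' maximum-intensity voxel; the segmentation itself happens upstream, and this
#' function consumes its outputs: VOI volume and mean activity concentration.
#' Residual activity at scan time is volume x concentration, then
#' decay-corrected back to injection time.
#'
#' @param voi_volume VOI volume, cm^3.
#' @param mean_concentration Mean activity concentration in the VOI, Bq/ml.
#' @param elapsed Minutes between injection and the PET acquisition
#'   (the uptake interval; 60 min is the routine FDG protocol value).
#' @param nuclide `"F18"` or `"Ga68"`.
#' @return A one-row tibble (`residual_activity`): `A_rs` (MBq at injection
#'   time), `A_scan` (MBq at scan time), provenance columns.
#' @examples
#' residual_from_pet(10.1, 111222, 60, "F18")
#' @export
residual_from_pet <- function(voi_volume, mean_concentration, elapsed = 60,
                              nuclide = "F18") {
  if (any(voi_volume < 0) || any(mean_concentration < 0)) {
    abort("Volume and concentration must be non-negative.",
          class = "radextra_data_error")
  }
  a_scan <- voi_volume * mean_concentration * 1e-6  # cm3 * Bq/ml -> MBq
  tibble::tibble(
    A_rs = decay_correct(a_scan, elapsed, nuclide),
    A_scan = a_scan,
    source = "pet_voi",
    voi_volume_cm3 = voi_volume,
    mean_concentration_Bq_ml = mean_concentration,
    elapsed_min = elapsed,
    nuclide = nuclide
  )
}

#' Residual activity from SPECT counts
#'
#' Converts a count rate in the segmented SPECT volume to activity through the
#' scanner's calibration factor (cps/MBq), then decay-corrects to injection
#' time. The Lu-177 calibration factor of the scanner used for the bundled
#' worked example is 11.75 cps/MBq.
#'
#' @param counts_rate Count rate in the VOI, cps.
#' @param calibration_factor Scanner calibration factor, cps/MBq (> 0).
#' @param elapsed Minutes between injection and the SPECT acquisition.
#' @param nuclide Nuclide (default `"Lu177"`).
#' @return A one-row tibble (`residual_activity`).
#' @export
residual_from_spect <- function(counts_rate, calibration_factor, elapsed = 0,
                                nuclide = "Lu177") {
  if (any(!is.finite(calibration_factor)) || any(calibration_factor <= 0)) {
    abort("`calibration_factor` must be positive.", class = "radextra_data_error")
  }
  if (any(counts_rate < 0)) {
    abort("`counts_rate` must be non-negative.", class = "radextra_data_error")
  }
  a_scan <- counts_rate / calibration_factor
  tibble::tibble(
    A_rs = decay_correct(a_scan, elapsed, nuclide),
    A_scan = a_scan,
    source = "spect_counts",
    counts_rate_cps = counts_rate,
    calibration_factor_cps_MBq = calibration_factor,
    elapsed_min = elapsed,
    nuclide = nuclide
  )
}

#' Sphere-model dose factor lookup
#'
#' Dose factors (mGy/MBq) come from an external sphere-model table computed
#' for discrete sphere masses; the factor for an arbitrary mass is obtained by
#' log-log linear interpolation between the bracketing table masses (dose
#' factors are close to a power law in mass). Queries outside the table are
#' clamped to the nearest entry and flagged.
#'
#' @param mass Query mass, g (vectorised).
#' @param table A data frame with positive, sorted columns `mass_g` and
#'   `dose_factor_mGy_MBq` (at least two rows).
#' @return A tibble with columns `mass_g`, `dose_factor_mGy_MBq`,
#'   `extrapolated`.
#' @export
dose_factor_lookup <- function(mass, table) {
  if (!is.data.frame(table) || nrow(table) < 2L ||
      !all(c("mass_g", "dose_factor_mGy_MBq") %in% names(table))) {
    abort("`table` needs >= 2 rows with columns mass_g, dose_factor_mGy_MBq.",
          class = "radextra_config_error")
  }
  m <- table$mass_g; f <- table$dose_factor_mGy_MBq
  if (any(m <= 0) || any(f <= 0) || is.unsorted(m, strictly = TRUE)) {
    abort("Table masses must be positive, strictly sorted; factors positive.",
          class = "radextra_config_error")
  }
  if (any(mass <= 0)) {
    abort("Query masses must be positive.", class = "radextra_data_error")
  }
  clamped <- pmin(pmax(mass, m[1L]), m[length(m)])
  out <- exp(approx(log(m), log(f), xout = log(clamped), method = "linear")$y)
  tibble::tibble(mass_g = mass,
                 dose_factor_mGy_MBq = out,
                 extrapolated = mass < m[1L] | mass > m[length(m)])
}

#' Local self-absorbed dose from residual activity
#'
#' The tissue self-dose in the extravasation region is the product of the
#' decay-corrected residual activity and the sphere-model dose factor at the
#' matching mass: dose (mGy) = A_rs (MBq) x dose_factor (mGy/MBq).
#'
#' @param A_rs Residual activity at injection time, MBq.
#' @param dose_factor Sphere-model dose factor, mGy/MBq.
#' @return Self-dose in mGy (vectorised).
#' @examples
#' self_dose(18.7, 27.6)
#' @export
self_dose <- function(A_rs, dose_factor) {
  if (any(A_rs < 0) || any(dose_factor < 0)) {
    abort("`A_rs` and `dose_factor` must be non-negative.",
          class = "radextra_data_error")
  }
  A_rs * dose_factor
}

#' SUV correction coefficient for an extravasated administration
#'
#' When part of the injected activity never reaches circulation, SUV values
#' computed with the nominal injected activity are underestimated. Correcting
#' the denominator by subtracting the residual activity is equivalent to
#' multiplying the image-derived SUV by
#' `SUV_corr_coeff = A_inj / (A_inj - A_rs)`. Normal (or clinically
#' irrelevant) administrations keep the coefficient exactly 1.
#'
#' @param A_inj Injected activity, MBq.
#' @param A_rs Residual activity at injection time, MBq (`0 <= A_rs < A_inj`).
#' @param label `"extravasation"` or `"normal"` (vectorised).
#' @return A tibble with `SUV_corr_coeff` (>= 1) and `SUV_pct_CR`
#'   (percentage SUV change, `100 * (coeff - 1)`).
#' @examples
#' suv_correction(200, 46.3, "extravasation")
#' @export
suv_correction <- function(A_inj, A_rs, label = "extravasation") {
  n <- max(length(A_inj), length(A_rs), length(label))
  A_inj <- rep_len(A_inj, n); A_rs <- rep_len(A_rs, n)
  label <- rep_len(label, n)
  if (any(A_rs < 0)) {
    abort("`A_rs` must be non-negative.", class = "radextra_data_error")
  }
  if (any(A_rs >= A_inj)) {
    abort("`A_rs` must be smaller than `A_inj`.", class = "radextra_data_error")
  }
  coeff <- ifelse(label == "normal", 1, A_inj / (A_inj - A_rs))
  tibble::tibble(SUV_corr_coeff = coeff, SUV_pct_CR = 100 * (coeff - 1))
}

#' Calibrate the SUV correction coefficient against a curve metric
#'
#' Across a cohort the SUV correction coefficient is linear in the
#' activity-normalised inter-arm offset (`delta_R_t_nor`) and in the inverse
#' of `delta_p_nor`: coeff = p1 * metric + p2, fitted by ordinary least
#' squares. Normal sessions enter the fit as points with coefficient exactly
#' 1. The residual standard error is reported as RMSE (sqrt(SSE / (n - 2))).
#'
#' @param data A data frame of calibration points.
#' @param metric Column with the metric values (tidy-eval).
#' @param coefficient Column with the SUV correction coefficients (tidy-eval).
#' @return An `suv_calibration` object with elements `p1`, `p2`, `r_squared`,
#'   `rmse`; see [tidy.suv_calibration()].
#' @export
fit_suv_calibration <- function(data, metric, coefficient) {
  stopifnot(is.data.frame(data))
  x <- dplyr::pull(data, {{ metric }})
  y <- dplyr::pull(data, {{ coefficient }})
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) {
    abort("At least 3 calibration points are required.",
          class = "radextra_data_error")
  }
  if (max(x) - min(x) <= .Machine$double.eps * max(abs(x), 1)) {
    abort("Metric values are constant; the calibration is degenerate.",
          class = "radextra_data_error")
  }
  mod <- lm(y ~ x)
  sse <- sum(stats::residuals(mod)^2)
  structure(list(p1 = unname(coef(mod)[2L]), p2 = unname(coef(mod)[1L]),
                 r_squared = summary(mod)$r.squared,
                 rmse = sqrt(sse / (length(x) - 2L)),
                 n = length(x), model = mod,
                 data = tibble::tibble(metric = x, coefficient = y)),
            class = "suv_calibration")
}

#' @export
print.suv_calibration <- function(x, ...) {
  cat(sprintf("<suv_calibration> coeff = %.4g * metric + %.4g  (R2 = %.3f, RMSE = %.3g, n = %d)\n",
              x$p1, x$p2, x$r_squared, x$rmse, x$n))
  invisible(x)
}

#' Predict SUV correction coefficients from a calibration
#' @param object An `suv_calibration`.
#' @param metric New metric values.
#' @param ... Unused.
#' @export
predict.suv_calibration <- function(object, metric, ...) {
  object$p1 * metric + object$p2
}

#' Tidy an SUV calibration fit
#' @param x An `suv_calibration`.
#' @param ... Unused.
#' @export
tidy.suv_calibration <- function(x, ...) {
  sm <- summary(x$model)$coefficients
  ci <- stats::confint(x$model)
  tibble::tibble(term = c("p2", "p1"),
                 estimate = sm[, 1L], std.error = sm[, 2L],
                 statistic = sm[, 3L], p.value = sm[, 4L],
                 conf.low = ci[, 1L], conf.high = ci[, 2L])
}

#' One-row summary of an SUV calibration fit
#' @param x An `suv_calibration`.
#' @param ... Unused.
#' @export
glance.suv_calibration <- function(x, ...) {
  tibble::tibble(p1 = x$p1, p2 = x$p2, r_squared = x$r_squared,
                 rmse = x$rmse, n = x$n)
}
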