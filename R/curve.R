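#' Construct and validate a dose-rate curve
#'
#' A dose-rate curve is the 1 Hz time series recorded by one wearable detector:
#' elapsed seconds against ambient dose equivalent rate H*(10) in uSv/h. The
#' constructor validates monotone time and non-negative dose rates and, when
#' the input is not sampled exactly at 1 s, resamples it onto an integer-second
#' grid by linear interpolation.
#'
#' @param data A data frame with numeric columns `time` (seconds) and
#'   `dose_rate` (uSv/h).
#' @param arm Which arm the detector was strapped to: `"injection"` or
#'   `"contralateral"`.
#' @param detector_id Optional free-text detector identifier.
#' @param resample Resample to 1 Hz when the native sampling differs
#'   (default `TRUE`). With `resample = FALSE` a non-1 Hz grid is an error.
#' @return A tibble of class `dr_curve` with columns `time` and `dose_rate`,
#'   carrying `arm` and `detector_id` attributes.
#' @examples
#' dose_rate_curve(data.frame(time = 0:5, dose_rate = c(2, 4, 90, 40, 20, 10)))
#' @export
dose_rate_curve <- function(data, arm = c("injection", "contralateral"),
                            detector_id = NA_character_, resample = TRUE) {
  arm <- match.arg(arm)
  if (!is.data.frame(data) || !all(c("time", "dose_rate") %in% names(data))) {
    abort("`data` must have columns `time` and `dose_rate`.",
          class = "radextra_format_error")
  }
  time <- as.double(data$time)
  dose <- as.double(data$dose_rate)
  if (anyNA(time) || anyNA(dose)) {
    abort("Curve contains missing or unparsable values.", class = "radextra_data_error")
  }
  if (length(time) < 2L) {
    abort("A curve needs at least two samples.", class = "radextra_data_error")
  }
  if (any(diff(time) <= 0)) {
    abort("Curve times must be strictly increasing.", class = "radextra_data_error")
  }
  if (any(time < 0)) {
    abort("Curve times must be non-negative.", class = "radextra_data_error")
  }
  if (any(dose < 0)) {
    abort("Dose rates must be non-negative.", class = "radextra_data_error")
  }
  if (!.is_1hz(time)) {
    if (!resample) {
      abort("Curve is not sampled at 1 Hz and `resample = FALSE`.",
            class = "radextra_data_error")
    }
    grid <- seq(time[1L], time[length(time)], by = 1)
    dose <- approx(time, dose, xout = grid, method = "linear")$y
    time <- grid
  }
  out <- tibble::tibble(time = time, dose_rate = dose)
  structure(out,
            arm = arm, detector_id = detector_id,
            class = c("dr_curve", class(out)))
}

.is_1hz <- function(time, tol = 1e-6) {
  all(abs(diff(time) - 1) < tol)
}

#' @export
print.dr_curve <- function(x, ...) {
  cat(sprintf("<dr_curve> arm = %s, %d samples, %.0f s, max %.1f uSv/h\n",
              attr(x, "arm"), nrow(x), x$time[nrow(x)] - x$time[1L],
              max(x$dose_rate)))
  NextMethod()
}

#' Arm label of a dose-rate curve
#' @param curve A `dr_curve`.
#' @return `"injection"` or `"contralateral"`.
#' @export
curve_arm <- function(curve) attr(curve, "arm")

#' Read a detector CSV export as a dose-rate curve
#'
#' Detector software exports one CSV per detector with a time column (elapsed
#' seconds or ISO-8601 timestamps) and a dose-rate column in uSv/h. The reader
#' is deliberately permissive about the dialect: the delimiter (comma or
#' semicolon) is auto-detected, decimal commas in semicolon-delimited exports
#' are accepted, and columns are matched by name (`time`/`timestamp`/`sec`,
#' `dose`/`rate`/`usv`) falling back to positional order. ISO timestamps are
#' converted to elapsed seconds from the first sample.
#'
#' @param path Path to the CSV file.
#' @inheritParams dose_rate_curve
#' @return A validated, 1 Hz [dose_rate_curve()].
#' @export
read_dose_curve <- function(path, arm = c("injection", "contralateral"),
                            detector_id = NULL) {
  arm <- match.arg(arm)
  if (!file.exists(path)) {
    abort(sprintf("File not found: %s", path), class = "radextra_format_error")
  }
  header <- readLines(path, n = 1L, warn = FALSE)
  semi <- lengths(regmatches(header, gregexpr(";", header, fixed = TRUE)))
  delim <- if (semi > 0L) ";" else ","
  loc <- readr::locale(decimal_mark = if (delim == ";") "," else ".")
  raw <- readr::read_delim(path, delim = delim, locale = loc,
                           col_types = readr::cols(.default = readr::col_character()),
                           trim_ws = TRUE, progress = FALSE,
                           show_col_types = FALSE)
  if (ncol(raw) < 2L || nrow(raw) == 0L) {
    abort(sprintf("Expected at least two columns in %s", path),
          class = "radextra_format_error")
  }
  nm <- tolower(names(raw))
  t_col <- which(grepl("time|sec|^t$", nm))[1L]
  d_col <- which(grepl("dose|rate|usv|µsv|value", nm) & !grepl("time", nm))[1L]
  if (is.na(t_col)) t_col <- 1L
  if (is.na(d_col)) d_col <- setdiff(seq_len(ncol(raw)), t_col)[1L]
  time <- .parse_time_column(raw[[t_col]], path)
  dose <- .parse_numeric_column(raw[[d_col]], delim)
  if (anyNA(dose)) {
    abort(sprintf("Unparsable dose-rate values in %s", path),
          class = "radextra_format_error")
  }
  dose_rate_curve(tibble::tibble(time = time, dose_rate = dose), arm = arm,
                  detector_id = detector_id %||% basename(path))
}

.parse_numeric_column <- function(x, delim) {
  # decimal commas appear in European exports even with comma delimiters when
  # the field is quoted; normalise "342,5" -> "342.5" where unambiguous
  x <- trimws(x)
  if (delim == ",") {
    only_comma <- grepl("^[0-9]+,[0-9]+$", x)
    x[only_comma] <- sub(",", ".", x[only_comma], fixed = TRUE)
  } else {
    x <- sub(",", ".", x, fixed = TRUE)
  }
  suppressWarnings(as.numeric(x))
}

.parse_time_column <- function(x, path) {
  num <- suppressWarnings(as.numeric(sub(",", ".", trimws(x), fixed = TRUE)))
  if (!anyNA(num)) return(num)
  ts <- suppressWarnings(readr::parse_datetime(trimws(x)))
  if (anyNA(ts)) {
    abort(sprintf("Unparsable time column in %s (need seconds or ISO-8601)", path),
          class = "radextra_format_error")
  }
  as.numeric(difftime(ts, ts[1L], units = "secs"))
}

#' Write a dose-rate curve to CSV
#'
#' Writes the two-column CSV dialect the reader accepts, so that
#' `read_dose_curve()` after `write_dose_curve()` is the identity on
#' validated curves.
#'
#' @param curve A `dr_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dose_curve <- function(curve, path) {
  stopifnot(inherits(curve, "dr_curve"))
  readr::write_csv(tibble::tibble(time = curve$time,
                                  dose_rate_uSv_h = curve$dose_rate),
                   path, progress = FALSE)
  invisible(path)
}

#' Pair arm curves and administration metadata into a session
#'
#' An injection session holds the injection-arm curve, optionally the
#' contralateral-arm curve (single-detector mode otherwise), and the
#' administration metadata needed downstream: injected activity, nuclide and
#' modality. Diagnostic sessions are F-18 or Ga-68 PET tracers; therapeutic
#' sessions are Lu-177 radioligand infusions.
#'
#' @param injection Injection-arm [dose_rate_curve()].
#' @param contralateral Contralateral-arm curve, or `NULL` for
#'   single-detector mode.
#' @param A_inj Injected activity in MBq (> 0).
#' @param nuclide `"F18"`, `"Ga68"` or `"Lu177"`.
#' @param modality `"diagnostic"` or `"therapeutic"`.
#' @param injection_start Optional infusion start time (s); when set it
#'   overrides the peak as the windowing anchor (useful for slow infusions
#'   whose curve has no bolus peak).
#' @param session_id Optional identifier carried into reports.
#' @param cfg Preprocessing configuration used to check that the two curves
#'   overlap by at least one analysis window; defaults to the modality's
#'   standard windows.
#' @return An `injection_session` object.
#' @export
injection_session <- function(injection, contralateral = NULL, A_inj, nuclide,
                              modality = c("diagnostic", "therapeutic"),
                              injection_start = NULL, session_id = NULL,
                              cfg = preprocess_config(modality)) {
  modality <- match.arg(modality)
  nuclide <- match.arg(nuclide, names(.half_lives_min))
  stopifnot(inherits(injection, "dr_curve"))
  .assert_scalar_num(A_inj, "A_inj", min = 0, strict = TRUE)
  if (modality == "therapeutic" && nuclide != "Lu177") {
    abort("Therapeutic sessions must use Lu177.", class = "radextra_config_error")
  }
  if (modality == "diagnostic" && nuclide == "Lu177") {
    abort("Diagnostic sessions must use F18 or Ga68.", class = "radextra_config_error")
  }
  win_len <- cfg$pre_peak_window + cfg$post_peak_window
  if (!is.null(contralateral)) {
    stopifnot(inherits(contralateral, "dr_curve"))
    overlap <- min(injection$time[nrow(injection)], contralateral$time[nrow(contralateral)]) -
      max(injection$time[1L], contralateral$time[1L])
    if (overlap < win_len) {
      abort(sprintf(
        "Arm curves overlap by %.0f s; the %s analysis window needs %.0f s.",
        overlap, modality, win_len), class = "radextra_data_error")
    }
  }
  dur <- injection$time[nrow(injection)] - injection$time[1L]
  if (dur < win_len) {
    abort(sprintf("Injection curve lasts %.0f s; the %s analysis window needs %.0f s.",
                  dur, modality, win_len), class = "radextra_data_error")
  }
  structure(list(
    injection = injection,
    contralateral = contralateral,
    A_inj = A_inj,
    nuclide = nuclide,
    modality = modality,
    injection_start = injection_start,
    session_id = session_id %||% "session",
    single_detector = is.null(contralateral)
  ), class = "injection_session")
}

#' @export
print.injection_session <- function(x, ...) {
  cat(sprintf("<injection_session> %s: %s %s, %.0f MBq, %s\n",
              x$session_id, x$modality, x$nuclide, x$A_inj,
              if (x$single_detector) "single detector" else "two detectors"))
  invisible(x)
}
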