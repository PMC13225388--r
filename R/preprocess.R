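#' Preprocessing configuration
#'
#' Window lengths, smoothing and plateau-stability constants. Diagnostic
#' acquisitions are cut one minute before and seven minutes after the bolus
#' peak (an 8-minute analysis window); therapeutic infusions two minutes
#' before and ten minutes after the anchor. The Gaussian filter starts 60 s
#' after the peak so the peak itself is never smoothed; plateau stability
#' requires successive 1 s samples to differ by at most 15 uSv/h for 60
#' consecutive seconds.
#'
#' @param modality `"diagnostic"` or `"therapeutic"`; sets the window defaults.
#' @param pre_peak_window,post_peak_window Seconds before/after the anchor.
#' @param smooth_delay Seconds after the anchor before smoothing begins.
#' @param gauss_sigma Gaussian kernel standard deviation, seconds.
#' @param stability_delta Maximum allowed successive-sample difference, uSv/h.
#' @param stability_duration Seconds the stability condition must hold.
#' @return A `preprocess_config` list.
#' @examples
#' preprocess_config("diagnostic")
#' @export
preprocess_config <- function(modality = c("diagnostic", "therapeutic"),
                              pre_peak_window = NULL, post_peak_window = NULL,
                              smooth_delay = 60, gauss_sigma = 5,
                              stability_delta = 15, stability_duration = 60) {
  modality <- match.arg(modality)
  pre <- pre_peak_window %||% if (modality == "diagnostic") 60 else 120
  post <- post_peak_window %||% if (modality == "diagnostic") 420 else 600
  for (v in c(pre = pre, post = post, smooth_delay = smooth_delay,
              gauss_sigma = gauss_sigma, stability_delta = stability_delta,
              stability_duration = stability_duration)) {
    .assert_scalar_num(v, "preprocess constant", min = 0, strict = TRUE)
  }
  structure(list(modality = modality,
                 pre_peak_window = pre, post_peak_window = post,
                 smooth_delay = smooth_delay, gauss_sigma = gauss_sigma,
                 stability_delta = stability_delta,
                 stability_duration = stability_duration),
            class = "preprocess_config")
}

#' Locate the bolus peak of a curve
#'
#' The anchor for all windowing is the global maximum of the raw (unsmoothed)
#' injection curve -- the passage of the radioactive bolus under the sensor.
#' Ties are broken by the earliest time.
#'
#' @param curve A `dr_curve`.
#' @return A tibble with columns `time`, `value` and `index`.
#' @examples
#' pk <- find_peak(dose_rate_curve(data.frame(time = 0:3, dose_rate = c(1, 5, 3, 2))))
#' @export
find_peak <- function(curve) {
  if (!inherits(curve, "dr_curve") || nrow(curve) == 0L) {
    abort("`curve` must be a non-empty dr_curve.", class = "radextra_data_error")
  }
  i <- which.max(curve$dose_rate)  # which.max returns the first maximum
  tibble::tibble(time = curve$time[i], value = curve$dose_rate[i], index = i)
}

#' Cut a curve to the analysis window around the anchor
#'
#' Keeps samples in `[anchor - pre_peak_window, anchor + post_peak_window]`,
#' clipped to the available data, and re-zeroes time to the window start. The
#' anchor position inside the window is recorded in the `peak_time` attribute
#' (used by the smoother and the plateau search).
#'
#' @param curve A `dr_curve`.
#' @param peak_time Anchor time in the curve's time coordinates, s.
#' @param cfg A [preprocess_config()].
#' @return A windowed `dr_curve` with attributes `peak_time`,
#'   `clipped_left`, `clipped_right`.
#' @export
window_curve <- function(curve, peak_time, cfg) {
  stopifnot(inherits(curve, "dr_curve"), inherits(cfg, "preprocess_config"))
  t0 <- curve$time[1L]; t1 <- curve$time[nrow(curve)]
  if (peak_time < t0 || peak_time > t1) {
    abort("`peak_time` lies outside the curve.", class = "radextra_data_error")
  }
  lo <- peak_time - cfg$pre_peak_window
  hi <- peak_time + cfg$post_peak_window
  keep <- curve$time >= lo - 1e-9 & curve$time <= hi + 1e-9
  if (!any(keep)) {
    abort("Analysis window contains no samples.", class = "radextra_data_error")
  }
  sub <- curve[keep, , drop = FALSE]
  start <- sub$time[1L]
  out <- dose_rate_curve(tibble::tibble(time = sub$time - start,
                                        dose_rate = sub$dose_rate),
                         arm = attr(curve, "arm"),
                         detector_id = attr(curve, "detector_id"))
  attr(out, "peak_time") <- peak_time - start
  attr(out, "clipped_left") <- lo < t0 - 1e-9
  attr(out, "clipped_right") <- hi > t1 + 1e-9
  out
}

# Discrete Gaussian kernel, truncated at 4 sigma, renormalised.
.gauss_kernel <- function(sigma) {
  r <- max(1L, ceiling(4 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2))
  k / sum(k)
}

# Convolve with reflect padding; output length equals input length.
.reflect_convolve <- function(x, kernel) {
  r <- (length(kernel) - 1L) %/% 2L
  n <- length(x)
  pad_l <- x[pmin(n, r:1 + 1L)]        # x[2], x[3], ... reflected about x[1]
  pad_r <- x[pmax(1L, n - (1:r))]      # reflected about x[n]
  ext <- c(pad_l, x, pad_r)
  out <- stats::filter(ext, kernel, method = "convolution", sides = 2)
  as.numeric(out[(r + 1L):(r + n)])
}

#' Smooth the plateau region of a windowed curve
#'
#' Applies a Gaussian filter (reflect-boundary convolution) only to samples at
#' or after `peak_time + smooth_delay`; everything earlier -- in particular the
#' bolus peak -- is returned bit-identical. The filter sees the full curve, so
#' there is no boundary artefact at the splice.
#'
#' @param curve A windowed `dr_curve`.
#' @param peak_time Anchor time in the windowed coordinates, s. Defaults to
#'   the `peak_time` attribute set by [window_curve()].
#' @param cfg A [preprocess_config()].
#' @return A `dr_curve` of the same length.
#' @export
smooth_after_peak <- function(curve, peak_time = attr(curve, "peak_time"), cfg) {
  stopifnot(inherits(curve, "dr_curve"), inherits(cfg, "preprocess_config"))
  if (is.null(peak_time)) {
    abort("`peak_time` is required (window the curve first or pass it).",
          class = "radextra_config_error")
  }
  sm <- .reflect_convolve(curve$dose_rate, .gauss_kernel(cfg$gauss_sigma))
  out_vals <- curve$dose_rate
  late <- curve$time >= peak_time + cfg$smooth_delay - 1e-9
  out_vals[late] <- pmax(sm[late], 0)
  out <- dose_rate_curve(tibble::tibble(time = curve$time, dose_rate = out_vals),
                         arm = attr(curve, "arm"),
                         detector_id = attr(curve, "detector_id"))
  attr(out, "peak_time") <- peak_time
  attr(out, "clipped_left") <- attr(curve, "clipped_left")
  attr(out, "clipped_right") <- attr(curve, "clipped_right")
  attr(out, "smoothed") <- TRUE
  out
}

# Window + smooth one arm against a given anchor (absolute time).
.prepare_arm <- function(curve, anchor_time, cfg) {
  win <- window_curve(curve, anchor_time, cfg)
  list(raw = win,
       smooth = smooth_after_peak(win, cfg = cfg))
}

# Resolve the windowing anchor of a session: injection_start overrides the
# raw-curve global maximum (slow infusions have no bolus peak).
.session_anchor <- function(session) {
  if (!is.null(session$injection_start)) {
    return(session$injection_start)
  }
  find_peak(session$injection)$time
}
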