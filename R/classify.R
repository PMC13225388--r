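#' Classification rule for extravasation screening
#'
#' The operational thresholds sit at the 0.5 probability of univariate
#' logistic fits on a labelled cohort: an administration is flagged as
#' extravasation when `delta_p_nor` falls at or below 0.30 (the
#' peak-to-plateau drop is too small for the injected activity) or when
#' `delta_R_t` is at or above 388 uSv/h (the arms never converge). Values
#' exactly at a threshold classify as extravasation: missing an event is
#' costlier than a false alarm.
#'
#' @param delta_p_nor_threshold Extravasation when `delta_p_nor` <= this.
#' @param delta_R_t_threshold Extravasation when `delta_R_t` >= this (uSv/h).
#' @param combination Which metrics participate: `"either"` (OR rule,
#'   two-detector default), `"delta_p_only"` (single-detector mode) or
#'   `"delta_R_only"` (therapy mode).
#' @return A `classification_rule` list.
#' @export
classification_rule <- function(delta_p_nor_threshold = 0.30,
                                delta_R_t_threshold = 388,
                                combination = c("either", "delta_p_only", "delta_R_only")) {
  combination <- match.arg(combination)
  .assert_scalar_num(delta_p_nor_threshold, "delta_p_nor_threshold", min = 0, strict = TRUE)
  .assert_scalar_num(delta_R_t_threshold, "delta_R_t_threshold", min = 0, strict = TRUE)
  structure(list(delta_p_nor_threshold = delta_p_nor_threshold,
                 delta_R_t_threshold = delta_R_t_threshold,
                 combination = combination),
            class = "classification_rule")
}

#' Classify sessions as normal or extravasation
#'
#' Applies a [classification_rule()] to one or more metric rows (as returned
#' by [compute_metrics()], or any data frame with the needed columns).
#' Therapeutic rows are always judged on `delta_R_t` alone; single-detector
#' diagnostic rows fall back to `delta_p_only` with a warning when the rule
#' asks for `either`.
#'
#' @param metrics A data frame with columns `delta_p_nor` and/or `delta_R_t`
#'   (plus optional `mode`/`modality` columns used to pick the per-row rule).
#' @param rule A [classification_rule()].
#' @return `metrics` with added columns `label` (`"normal"`/`"extravasation"`)
#'   and `triggered_by` (comma-separated triggering metrics, `""` for
#'   normal).
#' @export
classify_session <- function(metrics, rule = classification_rule()) {
  stopifnot(is.data.frame(metrics), inherits(rule, "classification_rule"))
  metrics <- tibble::as_tibble(metrics)
  n <- nrow(metrics)
  get_col <- function(nm) if (nm %in% names(metrics)) metrics[[nm]] else rep(NA_real_, n)
  dpn <- get_col("delta_p_nor")
  drt <- get_col("delta_R_t")
  mode <- if ("mode" %in% names(metrics)) metrics$mode
          else if ("modality" %in% names(metrics)) metrics$modality
          else rep("diagnostic", n)

  comb <- rep(rule$combination, n)
  comb[mode == "therapeutic"] <- "delta_R_only"
  fallback <- comb == "either" & is.na(drt) & !is.na(dpn)
  if (any(fallback)) {
    warn(sprintf(
      "%d session(s) lack delta_R_t; falling back to delta_p_only classification.",
      sum(fallback)))
    comb[fallback] <- "delta_p_only"
  }

  use_p <- comb %in% c("either", "delta_p_only")
  use_r <- comb %in% c("either", "delta_R_only")
  missing_p <- use_p & comb == "delta_p_only" & is.na(dpn)
  missing_r <- use_r & comb == "delta_R_only" & is.na(drt)
  if (any(missing_p) || any(missing_r)) {
    miss <- if (any(missing_p)) "delta_p_nor" else "delta_R_t"
    abort(sprintf("Required metric `%s` is missing for the configured rule.", miss),
          class = "radextra_config_error")
  }

  trig_p <- use_p & !is.na(dpn) & dpn <= rule$delta_p_nor_threshold
  trig_r <- use_r & !is.na(drt) & drt >= rule$delta_R_t_threshold
  triggered <- purrr::map2_chr(trig_p, trig_r, function(p, r) {
    paste(c(if (p) "delta_p_nor", if (r) "delta_R_t"), collapse = ",")
  })
  metrics$label <- ifelse(trig_p | trig_r, "extravasation", "normal")
  metrics$triggered_by <- triggered
  metrics
}

#' Refit a decision threshold by logistic regression
#'
#' Maximum-likelihood univariate logistic fit
#' P(extravasation | x) = 1 / (1 + exp(-(a + b x))); the operating threshold
#' is the value where the fitted probability crosses 0.5, x = -a/b. With
#' perfectly separated classes the maximum-likelihood slope diverges, so the
#' threshold is returned as the midpoint of the gap between the classes and
#' flagged.
#'
#' @param data A data frame of labelled metric values.
#' @param value Column holding the metric (tidy-eval).
#' @param label Column holding the class label (tidy-eval).
#' @param positive Label treated as the positive (extravasation) class.
#' @return A `threshold_fit` object; see [tidy.threshold_fit()] and
#'   [glance.threshold_fit()].
#' @examples
#' d <- data.frame(x = c(rnorm(30, 0.5, 0.05), rnorm(30, 0.3, 0.05)),
#'                 cls = rep(c("normal", "extravasation"), each = 30))
#' fit_threshold(d, x, cls)
#' @export
fit_threshold <- function(data, value, label, positive = "extravasation") {
  stopifnot(is.data.frame(data))
  x <- dplyr::pull(data, {{ value }})
  lab <- dplyr::pull(data, {{ label }})
  keep <- is.finite(x) & !is.na(lab)
  x <- x[keep]; lab <- lab[keep]
  y <- as.integer(lab == positive)
  if (length(unique(y)) < 2L) {
    abort("Both classes are required to fit a threshold.",
          class = "radextra_data_error")
  }
  if (sum(y) < 2L || sum(1 - y) < 2L) {
    abort("At least two examples of each class are required.",
          class = "radextra_data_error")
  }

  separated <- max(x[y == 1]) < min(x[y == 0]) || max(x[y == 0]) < min(x[y == 1])
  if (separated) {
    lo <- min(max(x[y == 1]), max(x[y == 0]))
    hi <- max(min(x[y == 1]), min(x[y == 0]))
    thr <- (lo + hi) / 2
    fit <- structure(list(threshold = thr, slope = NA_real_,
                          intercept = NA_real_, pseudo_r2 = 1,
                          separated = TRUE, n = length(y),
                          data = tibble::tibble(x = x, y = y)),
                     class = "threshold_fit")
    return(fit)
  }

  mod <- suppressWarnings(glm(y ~ x, family = binomial()))
  a <- unname(coef(mod)[1L]); b <- unname(coef(mod)[2L])
  ll_full <- as.numeric(stats::logLik(mod))
  ll_null <- as.numeric(stats::logLik(suppressWarnings(glm(y ~ 1, family = binomial()))))
  structure(list(threshold = -a / b, slope = b, intercept = a,
                 pseudo_r2 = 1 - ll_full / ll_null,  # McFadden
                 separated = FALSE, n = length(y),
                 model = mod, data = tibble::tibble(x = x, y = y)),
            class = "threshold_fit")
}

#' @export
print.threshold_fit <- function(x, ...) {
  cat(sprintf("<threshold_fit> threshold (P = 0.5): %.4g%s, n = %d, pseudo-R2 = %.3f\n",
              x$threshold, if (x$separated) " [perfect separation]" else "",
              x$n, x$pseudo_r2))
  invisible(x)
}

#' Tidy a logistic threshold fit
#' @param x A `threshold_fit`.
#' @param ... Unused.
#' @return One row per coefficient (`intercept`, `slope`, `threshold`).
#' @export
tidy.threshold_fit <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope", "threshold"),
                 estimate = c(x$intercept, x$slope, x$threshold))
}

#' One-row summary of a logistic threshold fit
#' @param x A `threshold_fit`.
#' @param ... Unused.
#' @export
glance.threshold_fit <- function(x, ...) {
  tibble::tibble(threshold = x$threshold, pseudo_r2 = x$pseudo_r2,
                 separated = x$separated, n = x$n)
}
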