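#' Plot the two arm curves of a session
#'
#' @param object An [injection_session()].
#' @param cfg Optional [preprocess_config()]; when given, the windowed and
#'   smoothed curves are drawn and the plateau start is marked.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.injection_session <- function(object, cfg = NULL, ...) {
  if (is.null(cfg)) {
    curves <- list(object$injection, object$contralateral)
  } else {
    prep <- preprocess_session(object, cfg)
    curves <- list(prep$injection$smooth,
                   if (!is.null(prep$contralateral)) prep$contralateral$smooth)
  }
  df <- purrr::map_dfr(purrr::compact(curves), function(cv) {
    tibble::tibble(time = cv$time, dose_rate = cv$dose_rate, arm = curve_arm(cv))
  })
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$dose_rate,
                                        colour = .data$arm)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time [s]", y = "dose rate H*(10) [µSv/h]",
                  title = object$session_id,
                  subtitle = sprintf("%s, %s, %.0f MBq", object$modality,
                                     object$nuclide, object$A_inj)) +
    ggplot2::theme_minimal()
  if (!is.null(cfg)) {
    prep <- preprocess_session(object, cfg)
    ps <- plateau_start(prep$injection$smooth, cfg, from_time = prep$anchor_rel)
    if (!is.na(ps)) {
      p <- p + ggplot2::geom_vline(xintercept = ps, linetype = "dashed")
    }
  }
  p
}

#' Plot a fitted logistic threshold
#'
#' @param object A `threshold_fit` from [fit_threshold()].
#' @param ... Unused.
#' @return A ggplot: labelled points, the fitted logistic curve and the
#'   P = 0.5 threshold.
#' @export
autoplot.threshold_fit <- function(object, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "metric", y = "P(extravasation)") +
    ggplot2::theme_minimal()
  if (!object$separated) {
    grid <- tibble::tibble(x = seq(min(d$x), max(d$x), length.out = 200))
    grid$p <- 1 / (1 + exp(-(object$intercept + object$slope * grid$x)))
    p <- p + ggplot2::geom_line(data = grid, ggplot2::aes(x = .data$x, y = .data$p))
  }
  p
}

#' Plot an SUV calibration fit
#'
#' @param object An `suv_calibration` from [fit_suv_calibration()].
#' @param ... Unused.
#' @return A ggplot of calibration points with the fitted line.
#' @export
autoplot.suv_calibration <- function(object, ...) {
  d <- object$data
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$coefficient)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$p1, intercept = object$p2) +
    ggplot2::labs(x = "curve metric", y = "SUV correction coefficient",
                  subtitle = sprintf("coeff = %.3g × metric + %.3g  (R² = %.2f, RMSE = %.3g)",
                                     object$p1, object$p2, object$r_squared, object$rmse)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
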