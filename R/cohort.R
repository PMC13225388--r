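#' Compare a metric between the normal and extravasation classes
#'
#' Two-sided unpaired two-sample test on a labelled metric: the Wilcoxon rank
#' sum test (exact below 50 total observations, normal approximation above)
#' or the Kolmogorov-Smirnov test. Alongside the test, the per-class median,
#' 95% range (2.5th-97.5th percentiles) and interquartile range are reported,
#' matching the reporting style used for these cohorts.
#'
#' @param data A data frame of labelled values.
#' @param value Metric column (tidy-eval).
#' @param label Class column (tidy-eval).
#' @param test `"wilcoxon"` or `"ks"`.
#' @return A list with `test` (one-row tibble: statistic, p_value) and
#'   `classes` (per-class summary tibble).
#' @export
compare_classes <- function(data, value, label, test = c("wilcoxon", "ks")) {
  test <- match.arg(test)
  x <- dplyr::pull(data, {{ value }})
  g <- as.character(dplyr::pull(data, {{ label }}))
  keep <- is.finite(x) & !is.na(g)
  x <- x[keep]; g <- g[keep]
  lv <- unique(g)
  if (length(lv) != 2L || any(table(g) < 2L)) {
    abort("Exactly two classes with >= 2 observations each are required.",
          class = "radextra_data_error")
  }
  a <- x[g == lv[1L]]; b <- x[g == lv[2L]]
  ht <- if (test == "wilcoxon") {
    suppressWarnings(wilcox.test(a, b, exact = (length(x) < 50L)))
  } else {
    suppressWarnings(ks.test(a, b))
  }
  classes <- tibble::tibble(label = lv) |>
    dplyr::rowwise() |>
    dplyr::mutate(values = list(x[g == .data$label]),
                  n = length(.data$values),
                  median = median(.data$values),
                  q2.5 = quantile(.data$values, 0.025, names = FALSE),
                  q97.5 = quantile(.data$values, 0.975, names = FALSE),
                  q25 = quantile(.data$values, 0.25, names = FALSE),
                  q75 = quantile(.data$values, 0.75, names = FALSE)) |>
    dplyr::ungroup() |>
    dplyr::select(-"values")
  list(test = tibble::tibble(test = test,
                             statistic = unname(ht$statistic),
                             p_value = ht$p.value),
       classes = classes)
}

#' Screen covariates for correlation with curve metrics
#'
#' Pearson correlation of every metric-covariate pair, with Holm step-down
#' adjustment of the p-values across the whole family and a significance flag
#' at alpha = 0.05. Constant covariates (zero variance among complete pairs)
#' are skipped with a note. This mirrors the routine check that demographic
#' and clinical covariates (age, weight, height, glucose, corticosteroid or
#' chemotherapy treatment) do not confound the curve metrics.
#'
#' @param data Cohort table: one row per session.
#' @param metrics Character vector of metric column names.
#' @param covariates Character vector of covariate column names.
#' @param alpha Significance level for the flag.
#' @return A tibble with one row per (metric, covariate) pair: `r`, `n`,
#'   `p_raw`, `p_adjusted`, `significant`, `note`.
#' @export
covariate_screen <- function(data, metrics, covariates, alpha = 0.05) {
  stopifnot(is.data.frame(data))
  missing_cols <- setdiff(c(metrics, covariates), names(data))
  if (length(missing_cols) > 0L) {
    abort(paste0("Columns not found: ", paste(missing_cols, collapse = ", ")),
          class = "radextra_config_error")
  }
  grid <- tidyr::expand_grid(metric = metrics, covariate = covariates)
  res <- purrr::pmap_dfr(grid, function(metric, covariate) {
    x <- as.numeric(data[[metric]])
    y <- as.numeric(data[[covariate]])
    ok <- is.finite(x) & is.finite(y)
    if (sum(ok) < 3L) {
      return(tibble::tibble(metric = metric, covariate = covariate,
                            r = NA_real_, n = sum(ok), p_raw = NA_real_,
                            note = "fewer than 3 complete pairs"))
    }
    if (sd(x[ok]) == 0 || sd(y[ok]) == 0) {
      return(tibble::tibble(metric = metric, covariate = covariate,
                            r = NA_real_, n = sum(ok), p_raw = NA_real_,
                            note = "constant variable; skipped"))
    }
    ct <- cor.test(x[ok], y[ok], method = "pearson")
    tibble::tibble(metric = metric, covariate = covariate,
                   r = unname(ct$estimate), n = sum(ok),
                   p_raw = ct$p.value, note = NA_character_)
  })
  res$p_adjusted <- NA_real_
  tested <- !is.na(res$p_raw)
  res$p_adjusted[tested] <- p.adjust(res$p_raw[tested], method = "holm")
  res$significant <- !is.na(res$p_adjusted) & res$p_adjusted < alpha
  res
}
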