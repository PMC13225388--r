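# Independent oracle implementations, deliberately written as plain loops so
# they share no code path with the package internals.

# Exhaustive scan for the plateau-stability rule: earliest sample i >= from_idx
# such that |v[j+1] - v[j]| <= delta for all j in i .. i+L-1. Returns index or NA.
oracle_plateau_idx <- function(v, delta, L, from_idx = 1L) {
  n <- length(v)
  for (i in from_idx:max(from_idx, n)) {
    if (i + L > n) return(NA_integer_)
    ok <- TRUE
    for (j in i:(i + L - 1L)) {
      if (abs(v[j + 1L] - v[j]) > delta + 1e-9) { ok <- FALSE; break }
    }
    if (ok) return(i)
  }
  NA_integer_
}

# Naive Gaussian smoother with reflect boundary handling.
oracle_gauss_smooth <- function(x, sigma) {
  r <- max(1L, ceiling(4 * sigma))
  w <- exp(-((-r:r)^2) / (2 * sigma^2))
  w <- w / sum(w)
  n <- length(x)
  reflect <- function(i) {
    # reflect about the end samples: index 0 -> 2, index n+1 -> n-1
    while (i < 1L || i > n) {
      if (i < 1L) i <- 2L - i
      if (i > n) i <- 2L * n - i
    }
    i
  }
  out <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    for (k in -r:r) acc <- acc + w[k + r + 1L] * x[reflect(i + k)]
    out[i] <- acc
  }
  out
}

# Manual linear interpolation.
oracle_linear_interp <- function(x, y, xout) {
  vapply(xout, function(q) {
    i <- max(which(x <= q + 1e-12))
    if (x[i] == q || i == length(x)) return(y[i])
    y[i] + (q - x[i]) / (x[i + 1L] - x[i]) * (y[i + 1L] - y[i])
  }, numeric(1))
}

# Noise-free metric oracle for a simulator scenario: evaluates the scenario's
# arm curves analytically and re-derives the diagnostic metric vector with the
# loop-based oracles above (window -> smooth -> plateau -> means).
oracle_noise_free_metrics <- function(cfg, activity_ref = 100) {
  t <- seq(0, cfg$duration, by = 1)
  on <- as.numeric(t >= cfg$peak_time)
  systemic <- cfg$systemic_plateau *
    (1 - exp(-pmax(t - cfg$peak_time, 0) / cfg$equilibration_tau)) * on
  inj <- cfg$background + cfg$extravasation_offset * on + systemic +
    cfg$peak_height * exp(-pmax(t - cfg$peak_time, 0) / cfg$peak_width) * on
  con <- cfg$background + systemic

  pcfg <- preprocess_config(cfg$modality)
  anchor <- if (isTRUE(cfg$use_injection_start)) cfg$peak_time else t[which.max(inj)]
  keep <- t >= anchor - pcfg$pre_peak_window & t <= anchor + pcfg$post_peak_window
  tw <- t[keep] - t[keep][1L]
  anchor_rel <- anchor - t[keep][1L]
  iw <- inj[keep]; cw <- con[keep]

  splice <- tw >= anchor_rel + pcfg$smooth_delay
  ism <- iw; ism[splice] <- oracle_gauss_smooth(iw, pcfg$gauss_sigma)[splice]
  csm <- cw; csm[splice] <- oracle_gauss_smooth(cw, pcfg$gauss_sigma)[splice]

  from_idx <- which(tw >= anchor_rel)[1L]
  L <- pcfg$stability_duration
  pi_in <- oracle_plateau_idx(ism, pcfg$stability_delta, L, from_idx)
  pi_con <- oracle_plateau_idx(csm, pcfg$stability_delta, L, from_idx)
  DR_in_mean <- mean(ism[pi_in:length(ism)])
  DR_con_mean <- mean(csm[pi_con:length(csm)])
  a_units <- cfg$A_inj / activity_ref

  if (cfg$modality == "therapeutic") {
    post <- which(tw >= anchor_rel & tw <= anchor_rel + 600)
    post5 <- which(tw >= anchor_rel & tw <= anchor_rel + 300)
    d <- ism - csm
    delta_R_t <- mean(d[post])
    list(delta_R_t = delta_R_t,
         delta_R_t_mean_5 = mean(d[post5]),
         delta_R_t_nor = delta_R_t / a_units,
         DR_in_mean = DR_in_mean,
         t_star = tw[pi_in] - anchor_rel)
  } else {
    DR_in_max <- max(iw)
    delta_p <- DR_in_max - DR_in_mean
    list(DR_in_max = DR_in_max, DR_in_mean = DR_in_mean,
         DR_con_mean = DR_con_mean,
         t_star = tw[pi_in] - anchor_rel,
         delta_p = delta_p,
         delta_p_nor = delta_p / (DR_in_max * a_units),
         delta_R_t = DR_in_mean - DR_con_mean,
         delta_R_t_nor = (DR_in_mean - DR_con_mean) / a_units)
  }
}

# Random piecewise test curves exercising the plateau rule: mixtures of noisy
# steps, ramps and flats, some of which never stabilise.
random_plateau_curve <- function(n = NULL) {
  n <- n %||% sample(80:300, 1L)
  v <- numeric(0)
  level <- runif(1, 0, 500)
  while (length(v) < n) {
    seg_n <- sample(10:120, 1L)
    kind <- sample(c("flat", "ramp", "jumpy"), 1L)
    seg <- switch(kind,
      flat = rep(level, seg_n) + runif(seg_n, -6, 6),
      ramp = level + cumsum(runif(seg_n, -25, 30)),
      jumpy = level + cumsum(sample(c(-30, 0, 40), seg_n, replace = TRUE)))
    seg <- pmax(seg, 0)
    level <- seg[length(seg)]
    v <- c(v, seg)
  }
  v[seq_len(n)]
}

make_curve <- function(values, arm = "injection", t0 = 0) {
  dose_rate_curve(tibble::tibble(time = t0 + seq_along(values) - 1,
                                 dose_rate = values), arm = arm)
}

# Unit in the last printed digit (values are printed with 0 or 1 decimals).
printed_ulp <- function(printed) {
  ifelse(abs(printed - round(printed)) < 1e-9, 1, 0.1)
}

# Tolerance for |printed_a * factor - printed_product|: the printed operand is
# itself rounded, so half its last-digit unit propagates through the product,
# plus half a unit of the printed product.
printed_product_tol <- function(printed_a, factor, printed_product) {
  0.5 * printed_ulp(printed_a) * factor + 0.5 * printed_ulp(printed_product) + 1e-9
}
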