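#' Window and smooth both arms of a session
#'
#' Resolves the session anchor (injection-curve global maximum, or the
#' `injection_start` override), windows both arm curves around it and applies
#' the after-peak Gaussian filter. This is the shared front end of
#' [compute_metrics()] and the plotting helpers.
#'
#' @param session An [injection_session()].
#' @param cfg A [preprocess_config()]; defaults to the session modality's.
#' @return A list with elements `anchor` (absolute s), `anchor_rel`
#'   (windowed s), `injection` and `contralateral`, each holding `raw` and
#'   `smooth` windowed curves (`contralateral` is `NULL` in single-detector
#'   mode).
#' @export
preprocess_session <- function(session, cfg = preprocess_config(session$modality)) {
  stopifnot(inherits(session, "injection_session"))
  anchor <- .session_anchor(session)
  inj <- .prepare_arm(session$injection, anchor, cfg)
  con <- if (!is.null(session$contralateral)) .prepare_arm(session$contralateral, anchor, cfg)
  list(anchor = anchor,
       anchor_rel = attr(inj$raw, "peak_time"),
       injection = inj, contralateral = con)
}

#' Find the plateau starting point of a curve
#'
#' The stability rule: the earliest sample `i` at or after the search start
#' such that every successive-sample difference in the following
#' `stability_duration` seconds satisfies |v(j+1) - v(j)| <= `stability_delta`
#' (15 uSv/h by default). Differences are taken in absolute value, so a
#' plateau approached from below qualifies too.
#'
#' @param curve A (smoothed, windowed) 1 Hz `dr_curve`.
#' @param cfg A [preprocess_config()].
#' @param from_time Time at which the search begins; defaults to the curve's
#'   `peak_time` attribute, else the first sample.
#' @return The plateau start time in the curve's time coordinates, or `NA`
#'   when no sample satisfies the rule ("no plateau": the session is
#'   unstable and plateau-based metrics are unavailable).
#' @export
plateau_start <- function(curve, cfg, from_time = NULL) {
  stopifnot(inherits(curve, "dr_curve"), inherits(cfg, "preprocess_config"))
  from_time <- from_time %||% attr(curve, "peak_time") %||% curve$time[1L]
  v <- curve$dose_rate
  n <- length(v)
  L <- as.integer(round(cfg$stability_duration))
  start_idx <- which(curve$time >= from_time - 1e-9)[1L]
  if (is.na(start_idx)) return(NA_real_)
  ok <- abs(diff(v)) <= cfg$stability_delta + 1e-9
  cs <- c(0L, cumsum(!ok))
  last_i <- n - L
  if (last_i < start_idx) return(NA_real_)
  cand <- start_idx:last_i
  hit <- cand[cs[cand + L] - cs[cand] == 0L]
  if (length(hit) == 0L) return(NA_real_)
  curve$time[hit[1L]]
}

.checkpoints_s <- c(60, 120, 180, 240, 300, 360, 480, 600)

#' Instantaneous inter-arm differences at fixed checkpoints
#'
#' For therapy sessions the inter-arm difference is also evaluated at fixed
#' times after the start of the injection: 60, 120, 180, 240, 300, 360, 480
#' and 600 s. Values are taken on the smoothed curves; checkpoints beyond the
#' acquired data are dropped.
#'
#' @param session A therapeutic [injection_session()] with both arm curves.
#' @param cfg A [preprocess_config()].
#' @param checkpoints Checkpoint times, seconds after the anchor.
#' @return A tibble with columns `checkpoint_s` and `delta_uSv_h`.
#' @export
checkpoint_deltas <- function(session, cfg = preprocess_config(session$modality),
                              checkpoints = .checkpoints_s) {
  stopifnot(inherits(session, "injection_session"))
  if (is.null(session$contralateral)) {
    abort("Checkpoint differences need both arm curves.",
          class = "radextra_config_error")
  }
  prep <- preprocess_session(session, cfg)
  d <- .pointwise_difference(prep)
  purrr::map_dfr(checkpoints, function(cp) {
    t_abs <- prep$anchor_rel + cp
    i <- which(abs(d$time - t_abs) < 0.5)
    if (length(i) == 0L) return(tibble::tibble())
    tibble::tibble(checkpoint_s = cp, delta_uSv_h = d$delta[i[1L]])
  })
}

# Smoothed injection-minus-contralateral difference on the common time grid.
.pointwise_difference <- function(prep) {
  inj <- prep$injection$smooth
  con <- prep$contralateral$smooth
  common <- intersect(round(inj$time, 6), round(con$time, 6))
  ii <- match(common, round(inj$time, 6))
  ic <- match(common, round(con$time, 6))
  tibble::tibble(time = inj$time[ii],
                 delta = inj$dose_rate[ii] - con$dose_rate[ic])
}

#' Compute the full metric vector of a session
#'
#' Diagnostic sessions: the raw-curve maximum `DR_in_max`, the plateau means
#' of both arms (`DR_in_mean`, `DR_con_mean`), the time-to-plateau `t_star`,
#' the peak-to-plateau drop `delta_p = DR_in_max - DR_in_mean`, its
#' normalisation `delta_p_nor = delta_p / (DR_in_max * A_inj / activity_ref)`
#' and the inter-arm plateau difference
#' `delta_R_t = DR_in_mean - DR_con_mean` (with its activity-normalised
#' variant `delta_R_t_nor`).
#'
#' Therapeutic sessions: infusion curves carry no bolus peak, so `DR_in_max`,
#' `delta_p` and `delta_p_nor` are not representative and are returned as
#' `NA`; `delta_R_t` is instead the mean of the pointwise smoothed inter-arm
#' difference over the first 10 minutes after the anchor, `delta_R_t_mean_5`
#' the same over the first 5 minutes, and the fixed checkpoints of
#' [checkpoint_deltas()] are reported as `delta_R_t_at_<s>` columns.
#'
#' Small peak-to-plateau drops relative to activity (low `delta_p_nor`) and
#' large persistent inter-arm offsets (high `delta_R_t`) are the two
#' extravasation signatures used by [classify_session()].
#'
#' @param session An [injection_session()].
#' @param cfg A [preprocess_config()].
#' @param activity_ref Reference activity (MBq) used as the unit of `A_inj`
#'   in the normalised metrics; default 100 MBq puts typical diagnostic
#'   normal administrations near `delta_p_nor` = 0.5.
#' @return A one-row tibble: session identifiers, mode flags, the metric
#'   columns described above, and `plateau_found`.
#' @export
compute_metrics <- function(session, cfg = preprocess_config(session$modality),
                            activity_ref = 100) {
  stopifnot(inherits(session, "injection_session"))
  .assert_scalar_num(activity_ref, "activity_ref", min = 0, strict = TRUE)
  prep <- preprocess_session(session, cfg)
  a_units <- session$A_inj / activity_ref

  pk <- find_peak(prep$injection$raw)
  ps_in <- plateau_start(prep$injection$smooth, cfg, from_time = prep$anchor_rel)
  plateau_found <- !is.na(ps_in)
  DR_in_mean <- if (plateau_found) {
    mean(prep$injection$smooth$dose_rate[prep$injection$smooth$time >= ps_in - 1e-9])
  } else NA_real_
  t_star <- if (plateau_found) ps_in - prep$anchor_rel else NA_real_

  DR_con_mean <- NA_real_
  if (!is.null(prep$contralateral)) {
    ps_con <- plateau_start(prep$contralateral$smooth, cfg, from_time = prep$anchor_rel)
    if (!is.na(ps_con)) {
      DR_con_mean <- mean(
        prep$contralateral$smooth$dose_rate[prep$contralateral$smooth$time >= ps_con - 1e-9])
    }
  }

  therapeutic <- session$modality == "therapeutic"
  if (therapeutic) {
    DR_in_max <- delta_p <- delta_p_nor <- NA_real_
  } else {
    DR_in_max <- pk$value
    delta_p <- if (plateau_found) DR_in_max - DR_in_mean else NA_real_
    delta_p_nor <- if (plateau_found) delta_p / (DR_in_max * a_units) else NA_real_
  }

  cp_cols <- setNames(rep(NA_real_, length(.checkpoints_s)),
                      paste0("delta_R_t_at_", .checkpoints_s))
  delta_R_t <- delta_R_t_mean_5 <- NA_real_
  if (!is.null(prep$contralateral)) {
    if (therapeutic) {
      d <- .pointwise_difference(prep)
      post <- d[d$time >= prep$anchor_rel - 1e-9, , drop = FALSE]
      in10 <- post$time <= prep$anchor_rel + 600 + 1e-9
      in5 <- post$time <= prep$anchor_rel + 300 + 1e-9
      delta_R_t <- mean(post$delta[in10])
      delta_R_t_mean_5 <- mean(post$delta[in5])
      cps <- checkpoint_deltas(session, cfg)
      cp_cols[paste0("delta_R_t_at_", cps$checkpoint_s)] <- cps$delta_uSv_h
    } else if (plateau_found && !is.na(DR_con_mean)) {
      delta_R_t <- DR_in_mean - DR_con_mean
    }
  }
  delta_R_t_nor <- delta_R_t / a_units

  mode <- if (session$single_detector) "single_detector" else session$modality
  tibble::tibble(
    session_id = session$session_id,
    modality = session$modality,
    mode = mode,
    A_inj = session$A_inj,
    nuclide = session$nuclide,
    anchor_time = prep$anchor,
    plateau_found = plateau_found,
    DR_in_max = DR_in_max,
    DR_in_mean = DR_in_mean,
    DR_con_mean = DR_con_mean,
    t_star = t_star,
    delta_p = delta_p,
    delta_p_nor = delta_p_nor,
    delta_R_t = delta_R_t,
    delta_R_t_nor = delta_R_t_nor,
    delta_R_t_mean_5 = delta_R_t_mean_5,
    !!!as.list(cp_cols)
  )
}
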