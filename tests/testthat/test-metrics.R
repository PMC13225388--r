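cfg_d <- preprocess_config("diagnostic")

test_that("plateau rule: constants, steps and ramps behave as specified", {
  # constant curve: plateau at the first searched sample
  const <- make_curve(rep(80, 200))
  expect_equal(plateau_start(const, cfg_d, from_time = 0), 0)
  expect_equal(plateau_start(const, cfg_d, from_time = 25), 25)

  # 20 uSv/h steps violate the rule; once steps shrink to 5 uSv/h the first
  # quiet sample starts the plateau
  v <- c(seq(0, by = 20, length.out = 121), seq(2405, by = 5, length.out = 120))
  stepc <- make_curve(v)
  got <- plateau_start(stepc, cfg_d, from_time = 0)
  exp_idx <- oracle_plateau_idx(v, 15, 60, 1L)
  expect_equal(got, stepc$time[exp_idx])
  expect_equal(exp_idx, 121L)  # first sample whose next 60 diffs are all 5

  # a 16 uSv/h/s ramp never satisfies the rule
  ramp <- make_curve(seq(0, by = 16, length.out = 200))
  expect_true(is.na(plateau_start(ramp, cfg_d, from_time = 0)))

  # too short after the search start -> no plateau
  shortc <- make_curve(rep(10, 30))
  expect_true(is.na(plateau_start(shortc, cfg_d, from_time = 0)))
})

test_that("plateau detection matches the exhaustive brute-force scan", {
  set.seed(101)
  for (i in 1:200) {
    v <- random_plateau_curve()
    cv <- make_curve(v)
    from_idx <- sample.int(max(1L, length(v) - 70L), 1L)
    got <- plateau_start(cv, cfg_d, from_time = cv$time[from_idx])
    want_idx <- oracle_plateau_idx(v, cfg_d$stability_delta,
                                   cfg_d$stability_duration, from_idx)
    if (is.na(want_idx)) {
      expect_true(is.na(got))
    } else {
      expect_equal(got, cv$time[want_idx])
    }
  }
})

make_session <- function(inj_vals, con_vals = NULL, A_inj = 187,
                         modality = "diagnostic", nuclide = "F18", ...) {
  injection_session(
    make_curve(inj_vals),
    if (!is.null(con_vals)) make_curve(con_vals, arm = "contralateral"),
    A_inj = A_inj, nuclide = nuclide, modality = modality, ...)
}

test_that("metric arithmetic is exact on noise-free plateaus", {
  # injection: clean peak then flat 300; contralateral flat 60
  inj <- c(rep(5, 60), 1000, rep(300, 540))
  con <- rep(60, 601)
  m <- compute_metrics(make_session(inj, con))
  expect_equal(m$DR_in_max, 1000)
  expect_equal(m$DR_in_mean, 300)
  expect_equal(m$DR_con_mean, 60)
  expect_equal(m$delta_R_t, 240)
  expect_equal(m$delta_p, 700)
  expect_true(m$plateau_found)
  expect_gte(m$t_star, 0)

  # the normalisation convention: DR_max 1000, plateau 100, 187 MBq -> ~0.481
  m2 <- compute_metrics(make_session(c(rep(5, 60), 1000, rep(100, 540)), con))
  expect_equal(m2$delta_p_nor, 0.9 / 1.87, tolerance = 1e-12)
})

test_that("delta_p_nor is scale-invariant and inversely proportional to A_inj", {
  inj <- c(rep(5, 60), 1000, rep(120, 540))
  con <- rep(60, 601)
  m1 <- compute_metrics(make_session(inj, con, A_inj = 187))
  m3 <- compute_metrics(make_session(inj * 3.7, con * 3.7, A_inj = 187))
  expect_equal(m3$delta_p_nor, m1$delta_p_nor, tolerance = 1e-12)
  m2x <- compute_metrics(make_session(inj, con, A_inj = 374))
  expect_equal(m2x$delta_p_nor, m1$delta_p_nor / 2, tolerance = 1e-12)
})

test_that("an injection-arm offset shifts delta_R_t by exactly that offset", {
  con <- rep(60, 601)
  base <- c(rep(5, 60), 1000, rep(60, 540))
  m0 <- compute_metrics(make_session(base, con))
  for (E in c(100, 400, 828)) {
    mE <- compute_metrics(make_session(base + c(rep(0, 60), rep(E, 541)), con))
    expect_equal(mE$delta_R_t - m0$delta_R_t, E, tolerance = 1e-9)
  }
})

test_that("single-detector sessions yield delta_p_nor but no inter-arm metrics", {
  m <- compute_metrics(make_session(c(rep(5, 60), 1000, rep(100, 540))))
  expect_equal(m$mode, "single_detector")
  expect_false(is.na(m$delta_p_nor))
  expect_true(is.na(m$delta_R_t))
  expect_true(is.na(m$DR_con_mean))
})

test_that("unstable curves are flagged and plateau metrics withheld", {
  ramp <- c(rep(5, 60), 10000, seq(9000, by = 16, length.out = 540))
  m <- compute_metrics(make_session(ramp, rep(60, 601)))
  expect_false(m$plateau_found)
  expect_true(is.na(m$DR_in_mean))
  expect_true(is.na(m$delta_p_nor))
  expect_true(is.na(m$delta_R_t))
})

therapy_session <- function(offset) {
  t <- 0:900
  inj <- 2 + offset * (t >= 150) + 150 * (1 - exp(-pmax(t - 150, 0) / 30)) * (t >= 150)
  con <- 2 + 150 * (1 - exp(-pmax(t - 150, 0) / 30)) * (t >= 150)
  injection_session(make_curve(inj), make_curve(con, arm = "contralateral"),
                    A_inj = 7250, nuclide = "Lu177", modality = "therapeutic",
                    injection_start = 150)
}

test_that("therapy mode: checkpoints and windowed means on constant offsets", {
  s0 <- therapy_session(0)
  cp0 <- checkpoint_deltas(s0)
  expect_equal(cp0$checkpoint_s, c(60, 120, 180, 240, 300, 360, 480, 600))
  expect_equal(cp0$delta_uSv_h, rep(0, 8), tolerance = 1e-9)

  s828 <- therapy_session(828)
  cp <- checkpoint_deltas(s828)
  expect_equal(cp$delta_uSv_h, rep(828, 8), tolerance = 1e-9)
  m <- compute_metrics(s828)
  expect_equal(m$delta_R_t, 828, tolerance = 1e-9)
  # 10-minute and 5-minute means agree exactly on constant offsets
  expect_equal(m$delta_R_t_mean_5, m$delta_R_t, tolerance = 1e-9)
  # peak-based metrics are not representative for infusions
  expect_true(is.na(m$DR_in_max))
  expect_true(is.na(m$delta_p_nor))
})

test_that("therapy checkpoints track an exponentially equilibrating offset", {
  t <- 0:900
  tau <- 90
  off <- 500
  # offset that decays towards a persistent 200 uSv/h residual
  extra <- (200 + off * exp(-pmax(t - 150, 0) / tau)) * (t >= 150)
  sys <- 150 * (1 - exp(-pmax(t - 150, 0) / 30)) * (t >= 150)
  s <- injection_session(make_curve(2 + sys + extra),
                         make_curve(2 + sys, arm = "contralateral"),
                         A_inj = 7250, nuclide = "Lu177",
                         modality = "therapeutic", injection_start = 150)
  cp <- checkpoint_deltas(s)
  # smoothing is mean-preserving to first order on the slow exponential
  expected <- 200 + off * exp(-cp$checkpoint_s / tau)
  expect_equal(cp$delta_uSv_h, expected, tolerance = 0.02)

  # checkpoints beyond the acquired data are dropped
  s_short <- injection_session(
    make_curve((2 + sys + extra)[1:750]),
    make_curve((2 + sys)[1:750], arm = "contralateral"),
    A_inj = 7250, nuclide = "Lu177", modality = "therapeutic",
    injection_start = 150)
  cp_short <- checkpoint_deltas(s_short)
  expect_false(600 %in% cp_short$checkpoint_s)
})

test_that("checkpoint differences require both arms", {
  inj <- c(rep(5, 150), rep(800, 751))
  s <- injection_session(make_curve(inj), NULL, A_inj = 7250,
                         nuclide = "Lu177", modality = "therapeutic",
                         injection_start = 150)
  expect_error(checkpoint_deltas(s), class = "radextra_config_error")
})
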