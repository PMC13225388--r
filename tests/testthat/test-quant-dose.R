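test_that("decay correction follows the physical half-life exactly", {
  expect_equal(decay_correct(1.0, 109.77, "F18"), 2.0)
  expect_equal(decay_correct(5.3, 0, "Ga68"), 5.3)
  expect_equal(decay_correct(2, 9573.1, "Lu177"), 4)
  expect_error(decay_correct(1, -5, "F18"), class = "radextra_data_error")
  # forward decay of the back-corrected value reproduces the input
  a0 <- decay_correct(3.7, 85, "F18")
  expect_equal(a0 * 2^(-85 / nuclide_half_life("F18")), 3.7, tolerance = 1e-12)
})

test_that("PET VOI statistics reproduce the worked-example residual activities", {
  cases <- dosimetry_cases("diagnostic")
  f18 <- cases[cases$nuclide == "F18", ]
  rec <- residual_from_pet(f18$volume_cm3, f18$mean_concentration_Bq_ml,
                           elapsed = 60, nuclide = "F18")
  # within 2% plus half a unit of the printed value's last digit
  expect_true(all(abs(rec$A_rs - f18$A_rs_MBq) <=
                    0.02 * f18$A_rs_MBq + 0.5 * printed_ulp(f18$A_rs_MBq)))
  # spot values
  expect_equal(residual_from_pet(10.1, 111222, 60, "F18")$A_rs, 1.6, tolerance = 0.03)
  expect_equal(residual_from_pet(14.9, 856960, 60, "F18")$A_rs, 18.7, tolerance = 0.02)
  expect_equal(residual_from_pet(0, 111222, 60, "F18")$A_rs, 0)
  expect_error(residual_from_pet(-1, 100, 60, "F18"), class = "radextra_data_error")
})

test_that("SPECT counts convert through the calibration factor", {
  expect_equal(residual_from_spect(11.75, 11.75, 0)$A_rs, 1.0)
  expect_equal(residual_from_spect(23.5, 11.75, 9573.1, "Lu177")$A_rs, 4.0)
  expect_equal(residual_from_spect(0, 11.75)$A_rs, 0)
  expect_error(residual_from_spect(10, 0), class = "radextra_data_error")
})

test_that("self-dose is the exact bilinear product", {
  expect_equal(self_dose(18.7, 27.6), 516.12)
  expect_equal(self_dose(286, 40.7), 11640.2)  # 11.6 Gy
  expect_equal(self_dose(0, 40.7), 0)
  expect_equal(self_dose(2 * 3.3, 16.5), 2 * self_dose(3.3, 16.5))
})

test_that("worked-example self-doses are reproduced within printed rounding", {
  cases <- dosimetry_cases("diagnostic")
  prod <- self_dose(cases$A_rs_MBq, cases$dose_factor_mGy_MBq)
  tol <- printed_product_tol(cases$A_rs_MBq, cases$dose_factor_mGy_MBq,
                             cases$self_dose_mGy)
  expect_true(all(abs(prod - cases$self_dose_mGy) <= tol))
  ther <- dosimetry_cases("therapy")
  expect_equal(self_dose(ther$A_rs_MBq, ther$dose_factor_mGy_MBq) / 1000,
               ther$self_dose_Gy, tolerance = 0.01)
})

test_that("sphere dose factors interpolate log-log with clamped extrapolation", {
  tab <- tibble::tibble(mass_g = c(1, 10, 100, 1000),
                        dose_factor_mGy_MBq = c(300, 60, 12, 2.4))
  expect_equal(dose_factor_lookup(10, tab)$dose_factor_mGy_MBq, 60)
  # geometric-mean mass -> geometric-mean factor
  expect_equal(dose_factor_lookup(sqrt(10 * 100), tab)$dose_factor_mGy_MBq,
               sqrt(60 * 12), tolerance = 1e-10)
  lo <- dose_factor_lookup(0.5, tab)
  expect_equal(lo$dose_factor_mGy_MBq, 300)
  expect_true(lo$extrapolated)
  hi <- dose_factor_lookup(5000, tab)
  expect_equal(hi$dose_factor_mGy_MBq, 2.4)
  expect_true(hi$extrapolated)
  expect_error(dose_factor_lookup(10, tab[1, ]), class = "radextra_config_error")
  expect_error(dose_factor_lookup(-1, tab), class = "radextra_data_error")
})

test_that("SUV correction: identity for normal sessions, A_inj/(A_inj - A_rs) otherwise", {
  expect_equal(suv_correction(200, 50, "normal")$SUV_corr_coeff, 1)
  expect_equal(suv_correction(200, 0)$SUV_corr_coeff, 1)
  got <- suv_correction(200, 46.3)
  expect_equal(got$SUV_corr_coeff, 200 / 153.7)
  expect_equal(got$SUV_pct_CR, 30.1, tolerance = 0.002)
  # strictly increasing in A_rs
  coeffs <- suv_correction(200, c(0, 10, 50, 120, 190))$SUV_corr_coeff
  expect_true(all(diff(coeffs) > 0))
  expect_error(suv_correction(200, 200), class = "radextra_data_error")
  expect_error(suv_correction(200, -1), class = "radextra_data_error")
})

test_that("the printed SUV change maximum corresponds to ~23% residual fraction", {
  # coeff = 1.301 <=> A_rs / A_inj = 1 - 1/1.301
  frac <- 1 - 1 / 1.301
  expect_equal(frac, 0.2314, tolerance = 1e-3)
  expect_equal(suv_correction(100, 100 * frac)$SUV_pct_CR, 30.1, tolerance = 1e-3)
})

test_that("SUV calibration: exact on a line, parameter recovery under noise", {
  d <- tibble::tibble(x = c(0.2, 0.5, 1.1, 2.0, 3.5), y = 2 * x + 1)
  fit <- suppressWarnings(fit_suv_calibration(d, x, y))
  expect_equal(fit$p1, 2, tolerance = 1e-12)
  expect_equal(fit$p2, 1, tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$rmse, 0, tolerance = 1e-10)

  # synthetic calibration with residual sigma = 0.02: coefficients recovered
  # within their 95% CIs, RMSE reported near 0.02
  sim <- withr::with_seed(31, {
    x <- c(runif(40, 0, 3), rep(0.05, 10))
    tibble::tibble(x = x, y = 0.12 * x + 1 + rnorm(length(x), 0, 0.02))
  })
  fit2 <- fit_suv_calibration(sim, x, y)
  td <- tidy(fit2)
  expect_true(td$conf.low[td$term == "p1"] <= 0.12 &&
              0.12 <= td$conf.high[td$term == "p1"])
  expect_true(td$conf.low[td$term == "p2"] <= 1 &&
              1 <= td$conf.high[td$term == "p2"])
  expect_equal(fit2$rmse, 0.02, tolerance = 0.3)

  expect_error(fit_suv_calibration(tibble::tibble(x = rep(1, 5), y = 1:5), x, y),
               class = "radextra_data_error")
  expect_error(fit_suv_calibration(d[1:2, ], x, y), class = "radextra_data_error")
})

test_that("normal sessions pooled at coefficient 1 anchor the calibration intercept", {
  d <- withr::with_seed(8, {
    x <- runif(40, 0.5, 4)
    tibble::tibble(metric = c(rep(0, 40), x),
                   coeff = c(rep(1, 40), 1 + 0.08 * x + rnorm(40, 0, 0.01)))
  })
  fit <- fit_suv_calibration(d, metric, coeff)
  expect_equal(fit$p2, 1, tolerance = 0.01)
})
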