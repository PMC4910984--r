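test_that("noiseless parabolic series: generating parameters recovered", {
  ser <- synthetic_power_series(d = 2, nu = 0.5, T0 = 9100)
  fit <- fit_power_law(ser)
  expect_equal(fit$nu, 0.5, tolerance = 1e-3)
  expect_equal(fit$d, 2, tolerance = 1e-2)
  expect_lt(fit$sse, 1e-6 * 9100^2)
})

test_that("exponential input pins the power-law exponent at its bound", {
  t <- 0:120
  ser <- lysis_series(t, 9100 * exp(-0.04 * t))
  pw <- fit_power_law(ser)
  expect_gt(pw$nu, 0.99)
  ex <- fit_exponential(ser)
  expect_equal(ex$d, 0.04, tolerance = 1e-3)
  cmp <- compare_decay_models(ser)
  expect_equal(cmp$preferred, "exponential")
})

test_that("parabolic input is preferred over exponential and vice versa", {
  ser_p <- synthetic_power_series(d = 2, nu = 0.5, T0 = 9100)
  cmp_p <- compare_decay_models(ser_p)
  expect_equal(cmp_p$preferred, "power_law")
  expect_gt(cmp_p$exponential$sse, cmp_p$power_law$sse)
})

test_that("degenerate series are refused", {
  expect_error(fit_power_law(lysis_series(0:10, rep(500, 11))), "constant")
  expect_error(fit_exponential(lysis_series(0:2, c(3, 2, 1))), "4 points")
})

test_that("2% multiplicative noise: median recovered nu within 0.02", {
  set.seed(11)
  nus <- replicate(50, {
    ser <- synthetic_power_series(d = 2, nu = 0.5, T0 = 9100,
                                  noise_sd = 0.02)
    fit_power_law(ser)$nu
  })
  expect_lt(abs(median(nus) - 0.5), 0.02)
})

test_that("SSE is invariant under joint time/d rescaling", {
  ser <- synthetic_power_series(d = 2, nu = 0.5, T0 = 5000, noise_sd = 0.01)
  fit1 <- fit_power_law(ser)
  # minutes instead of hours: t -> 60 t, d -> d/60
  ser2 <- lysis_series(ser$time_hr * 60, ser$tumor_cells)
  fit2 <- fit_power_law(ser2)
  expect_equal(fit2$sse, fit1$sse, tolerance = 1e-3)
  expect_equal(fit2$d * 60, fit1$d, tolerance = 1e-4)
  expect_equal(fit2$nu, fit1$nu, tolerance = 1e-4)
})

test_that("decay_fit methods: coef, predict, residuals, summary, simulate", {
  ser <- synthetic_power_series(d = 2, nu = 0.5, T0 = 9100,
                                noise_sd = 0.01)
  fit <- fit_power_law(ser)
  expect_named(coef(fit), c("d", "nu"))
  expect_equal(predict(fit, 0), fit$T0)
  expect_equal(length(residuals(fit)), fit$n_points)
  expect_equal(fit$data$tumor_cells - fit$fitted, residuals(fit))
  sm <- summary(fit)
  expect_gt(sm$r_squared, 0.999)
  sim <- simulate(fit, nsim = 2, seed = 1)
  expect_length(sim, 2)
  expect_s3_class(sim[[1]], "lysis_series")
  expect_output(print(fit), "power_law")
})

test_that("fit window drops the sub-2% stochastic tail", {
  ser <- synthetic_power_series(d = 2, nu = 0.5, T0 = 10000)
  # corrupt the terminal tail only; fit should be unaffected
  bad <- ser
  tail_idx <- bad$tumor_cells < 0.02 * 10000
  bad$tumor_cells[tail_idx] <- 100
  fit <- fit_power_law(bad)
  expect_equal(fit$nu, 0.5, tolerance = 5e-3)
})

test_that("lysis series CSV round-trip", {
  ser <- synthetic_power_series(d = 1, nu = 0.5, T0 = 100)
  path <- withr::local_tempfile(fileext = ".csv")
  write_lysis_series(ser, path)
  back <- read_lysis_series(path)
  expect_equal(back$tumor_cells, ser$tumor_cells)
  expect_equal(names(read.csv(path))[1:2], c("time_hr", "tumor_cells"))
})
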