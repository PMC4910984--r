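test_that("fractional cell kill matches hand-evaluated values", {
  kp <- kill_params(d = 1, lambda = 1, s = 1, nu = 1)
  # no effectors, no kill
  expect_identical(fractional_cell_kill(kp, E = 0, T = 100), 0)
  # E^lambda = s*T: half of the maximum d
  expect_equal(fractional_cell_kill(kp, E = 50, T = 50), 0.5)
  # general exponents: d*E^l/(s*T^nu + E^l) = 2*4/(3*4 + 4)
  kp2 <- kill_params(d = 2, lambda = 0.5, s = 3, nu = 2 / 3)
  expect_equal(fractional_cell_kill(kp2, E = 16, T = 8),
               2 * 4 / (3 * 8^(2 / 3) + 4))
  # removable singularity at the origin
  expect_identical(fractional_cell_kill(kp, E = 0, T = 0), 0)
})

test_that("kill rate saturates at d and is monotone in E and T", {
  kp <- kill_params(d = 0.7, lambda = 0.8, s = 2, nu = 0.9)
  E <- 10^(1:9)
  K <- fractional_cell_kill(kp, E, T = rep(1000, 9))
  expect_true(all(K < kp$d))
  expect_true(all(diff(K) > 0))           # increasing in E
  expect_lt(kp$d - K[9], 1e-4)            # -> d as E -> Inf
  Tv <- 10^(1:9)
  K2 <- fractional_cell_kill(kp, E = rep(100, 9), T = Tv)
  expect_true(all(diff(K2) < 0))          # decreasing in T
})

test_that("parameter and state validation errors are raised", {
  expect_error(kill_params(d = -1), "'d'")
  expect_error(kill_params(d = 1, lambda = 1.5), "lambda")
  expect_error(kill_params(d = 1, nu = 0), "nu")
  kp <- kill_params(d = 1)
  expect_error(fractional_cell_kill(kp, E = -1, T = 5), "non-negative")
})

test_that("decay RHS is -K*T^nu, non-positive, zero at extinction", {
  kp <- kill_params(d = 1, lambda = 1, s = 1, nu = 1)
  expect_identical(decay_rhs(kp, E = 50, T = 0), 0)
  expect_equal(decay_rhs(kp, E = 50, T = 50), -25)  # K = 0.5, T = 50
  # exponential limit: E^lambda >> s*T^nu gives -d*T
  kp2 <- kill_params(d = 0.04, lambda = 1, s = 1, nu = 1)
  expect_equal(decay_rhs(kp2, E = 1e6, T = 10), -0.4, tolerance = 1e-4)
  # continuity/non-positivity on a random grid
  set.seed(42)
  for (i in 1:50) {
    kp3 <- kill_params(d = runif(1, 0.1, 5), lambda = runif(1, 0.1, 1),
                       s = runif(1, 0.1, 10), nu = runif(1, 0.1, 1))
    r <- decay_rhs(kp3, E = runif(1, 0, 1e4), T = runif(1, 0, 1e4))
    expect_true(is.finite(r) && r <= 0)
  }
})

test_that("linear limit rate d*E0^lambda/s and T -> Inf agreement", {
  kp <- kill_params(d = 1, lambda = 1, s = 1, nu = 1)
  expect_equal(linear_limit_rate(kp, E0 = 1), 1)  # one cell per hour
  expect_identical(linear_limit_rate(kp, E0 = 0), 0)
  kp2 <- kill_params(d = 3, lambda = 0.5, s = 2, nu = 0.7)
  expect_equal(linear_limit_rate(kp2, E0 = 16), 6)  # 3*4/2
  # the decay RHS approaches the linear rate as T grows, any nu
  expect_equal(-decay_rhs(kp2, E = 16, T = 1e12),
               linear_limit_rate(kp2, E0 = 16), tolerance = 1e-3)
})

test_that("closed-form power decay: values, extinction, nu = 1 refusal", {
  expect_equal(closed_form_power_decay(d = 2, nu = 0.5, T0 = 100, t = 0), 100)
  # (sqrt(100) - 1*5)^2 = 25 at t = 5; extinct at t* = 2*sqrt(T0)/d = 10
  expect_equal(closed_form_power_decay(d = 2, nu = 0.5, T0 = 100, t = 5), 25)
  expect_equal(power_decay_extinction_time(d = 2, nu = 0.5, T0 = 100), 10)
  expect_identical(closed_form_power_decay(d = 2, nu = 0.5, T0 = 100,
                                           t = 11), 0)
  expect_error(closed_form_power_decay(d = 2, nu = 1, T0 = 100, t = 1),
               "nu")
})

test_that("integrate_decay reproduces the analytic limits", {
  # E0 = 0: nothing happens
  kp <- kill_params(d = 1, lambda = 1, s = 1, nu = 1)
  s0 <- integrate_decay(kp, T0 = 50, E0 = 0, t_grid = 0:10)
  expect_true(all(s0$tumor_cells == 50))

  # exponential limit (nu = 1, E^lambda >> s*T0)
  kp1 <- kill_params(d = 0.1, lambda = 1, s = 1, nu = 1)
  tg <- seq(0, 40, by = 0.5)
  s1 <- integrate_decay(kp1, T0 = 100, E0 = 1e7, t_grid = tg)
  expect_equal(s1$tumor_cells, 100 * exp(-0.1 * tg), tolerance = 1e-4)

  # parabolic limit (nu = 1/2, saturated)
  kp2 <- kill_params(d = 2, lambda = 1, s = 1, nu = 0.5)
  tg2 <- seq(0, 9.5, by = 0.25)
  s2 <- integrate_decay(kp2, T0 = 100, E0 = 1e8, t_grid = tg2)
  expect_equal(s2$tumor_cells,
               closed_form_power_decay(2, 0.5, 100, tg2), tolerance = 1e-4)

  # linear limit: E0^lambda/(s*T0^nu) < 1e-3 stays within 1% of the ramp
  kp3 <- kill_params(d = 1, lambda = 1, s = 1, nu = 1)
  T0 <- 1e5; E0 <- 10   # ratio 1e-4
  v <- linear_limit_rate(kp3, E0)
  half <- 0.5 * T0 / v
  tg3 <- seq(0, half, length.out = 51)
  s3 <- integrate_decay(kp3, T0, E0, tg3)
  expect_equal(s3$tumor_cells, T0 - v * tg3, tolerance = 0.01)

  # monotone non-increasing, clamped at zero after extinction
  s4 <- integrate_decay(kp2, T0 = 100, E0 = 1e8, t_grid = seq(0, 20, 0.5))
  expect_true(all(diff(s4$tumor_cells) <= 1e-9))
  expect_true(all(s4$tumor_cells >= 0))
  expect_equal(s4$tumor_cells[s4$time_hr > 10.5], rep(0, sum(s4$time_hr > 10.5)))
})

test_that("effectiveness rescaling s -> s/f^lambda is exact", {
  kp <- kill_params(d = 1, lambda = 1, s = 1, nu = 1)
  expect_equal(effectiveness_rescale(kp, 1), kp)
  kp_r <- effectiveness_rescale(kp, 0.5)
  expect_equal(kp_r$s, 2)
  expect_equal(fractional_cell_kill(kp_r, E = 10, T = 10),
               fractional_cell_kill(kp, E = 5, T = 10))
  # lambda = 2 is outside the valid (0,1] range; check the exponent
  # arithmetic at the boundary lambda = 1 and below instead, randomized
  set.seed(7)
  for (i in 1:100) {
    kp2 <- kill_params(d = runif(1, 0.1, 5), lambda = runif(1, 0.05, 1),
                       s = runif(1, 0.1, 10), nu = runif(1, 0.05, 1))
    f <- runif(1, 0.01, 1)
    E <- runif(1, 0, 1e4); T <- runif(1, 0, 1e4)
    expect_equal(fractional_cell_kill(effectiveness_rescale(kp2, f), E, T),
                 fractional_cell_kill(kp2, f * E, T), tolerance = 1e-12)
  }
  expect_error(effectiveness_rescale(kp, 0), "'f'")
})

test_that("kill parameters round-trip through JSON", {
  kp <- kill_params(d = 1.34, lambda = 0.8, s = 2.5, nu = 0.5)
  path <- withr::local_tempfile(fileext = ".json")
  write_kill_params(kp, path)
  expect_equal(read_kill_params(path), kp)
})
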