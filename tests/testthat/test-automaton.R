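# Small-lattice configuration used throughout: keeps the nutrient solves
# and sweeps fast while exercising every rule.
small_cfg <- function(...) {
  args <- list(n = 61, alpha = 2 / 61, lambda_N = 25, target_size = 600)
  ovr <- list(...)
  args[names(ovr)] <- ovr
  do.call(ca_config, args)
}

test_that("nutrient fields: Laplace limit, symmetry, tumor sink", {
  cfg <- small_cfg()
  empty <- matrix(0L, cfg$n, cfg$n)
  class(empty) <- "ca_grid"

  # zero consumption: uniform field at the vessel value
  zero_cfg <- small_cfg(lambda_N = 1)
  zero_cfg$alpha <- 1e-12
  f0 <- solve_nutrients(empty, zero_cfg, fields = "N")$N
  expect_equal(max(abs(f0 - 1)), 0, tolerance = 1e-8)

  # uniform consumption: symmetric about the vertical midline, in (0, 1]
  fN <- solve_nutrients(empty, cfg, fields = "N")$N
  expect_equal(fN, fN[, rev(seq_len(cfg$n))], tolerance = 1e-10)
  expect_true(all(fN > 0 & fN <= 1))
  expect_equal(fN[1, ], fN[cfg$n, ], tolerance = 1e-10)  # periodic rows

  # central tumor blob: the field minimum sits inside the blob
  g <- unclass(empty)
  g[28:34, 28:34] <- 1L
  class(g) <- "ca_grid"
  fT <- solve_nutrients(g, cfg, fields = "N")$N
  minpos <- which(fT == min(fT), arr.ind = TRUE)[1, ]
  expect_true(minpos[1] %in% 28:34 && minpos[2] %in% 28:34)
  expect_lt(min(fT), min(fN))
})

test_that("growth reaches the target within 2% and respects edge cases", {
  cfg <- small_cfg()
  grid <- grow_tumor(cfg, seed = 1)
  n_tumor <- sum(grid == 1L)
  expect_lte(abs(n_tumor - cfg$target_size) / cfg$target_size, 0.02)
  # single-cell target returns the seed alone
  g1 <- grow_tumor(small_cfg(target_size = 1), seed = 1)
  expect_equal(sum(g1 == 1L), 1L)
  # division switched off: growth stalls with an error
  expect_error(grow_tumor(small_cfg(theta_div = 0), seed = 1), "stalled")
})

test_that("growth is reproducible under a fixed seed", {
  cfg <- small_cfg()
  g1 <- grow_tumor(cfg, seed = 7)
  g2 <- grow_tumor(cfg, seed = 7)
  expect_identical(unclass(g1), unclass(g2))
})

test_that("immune placement fills the gamma sector of the circumscribed disk", {
  cfg <- small_cfg()
  grid <- grow_tumor(cfg, seed = 2)
  full <- place_immune_cells(grid, 2 * pi, cfg)
  half <- place_immune_cells(grid, pi, cfg)
  n_full <- sum(full == 2L)
  n_half <- sum(half == 2L)
  expect_gt(n_full, 0)
  # half the angle covers about half the sites
  expect_equal(n_half / n_full, 0.5, tolerance = 0.1)
  # gamma = 2*pi leaves no uncovered non-tumor site inside the circle:
  # every healthy site adjacent to tumor must be immune or vessel-column
  g <- unclass(full)
  tum <- which(g == 1L, arr.ind = TRUE)
  ctr <- colMeans(tum)
  rad <- sqrt(max((tum[, 1] - ctr[1])^2 + (tum[, 2] - ctr[2])^2))
  ij <- which(g == 0L, arr.ind = TRUE)
  inside <- (ij[, 1] - ctr[1])^2 + (ij[, 2] - ctr[2])^2 <= rad^2
  not_vessel <- ij[, 2] > 1 & ij[, 2] < cfg$n
  expect_equal(sum(inside & not_vessel), 0)
  expect_error(place_immune_cells(grid, 0, cfg), "gamma")
  expect_error(place_immune_cells(grid, 7, cfg), "gamma")
})

test_that("lysis conserves sites, never grows the tumor, and terminates", {
  cfg <- small_cfg()
  grid <- grow_tumor(cfg, seed = 3)
  g2 <- place_immune_cells(grid, 2 * pi, cfg)
  total <- cfg$n^2
  expect_equal(sum(g2 == 0L) + sum(g2 == 1L) + sum(g2 == 2L), total)
  ser <- run_lysis(g2, cfg, seed = 103)
  expect_true(all(diff(ser$tumor_cells) <= 0))
  expect_equal(ser$tumor_cells[1], sum(grid == 1L))
  # eradication on a fully covered small tumor
  expect_equal(ser$tumor_cells[nrow(ser)], 0)
})

test_that("no immune cells means no decay", {
  cfg <- small_cfg()
  grid <- grow_tumor(cfg, seed = 4)
  ser <- run_lysis(grid, cfg, seed = 104, max_steps = 50)
  expect_true(all(ser$tumor_cells == sum(grid == 1L)))
})

test_that("lysis runs are reproducible under a fixed seed", {
  cfg <- small_cfg()
  grid <- grow_tumor(cfg, seed = 5)
  g2 <- place_immune_cells(grid, 2 * pi, cfg)
  s1 <- run_lysis(g2, cfg, seed = 42)
  s2 <- run_lysis(g2, cfg, seed = 42)
  expect_identical(s1$tumor_cells, s2$tumor_cells)
  expect_identical(s1$immune_cells, s2$immune_cells)
})

test_that("near-certain lysis with instant recruitment peels layers", {
  # theta_lys, theta_rec -> 0+ make lysis and recruitment certain; the
  # frozen tumor then erodes like mask layer-peeling, at an effective
  # radial speed somewhat below one layer per hour (an effector adjacent
  # to several boundary tumor cells still lyses only one per hour), so
  # the two area curves are compared after rescaling time by the speed
  # ratio: the decay SHAPES must agree within 5% of the initial area
  cfg <- small_cfg(n = 101, target_size = 2500,
                   theta_lys = 0.05, theta_rec = 0.05, theta_inc = 0.05)
  grid <- grow_tumor(cfg, seed = 6)
  g2 <- place_immune_cells(grid, 2 * pi, cfg)
  ser <- run_lysis(g2, cfg, seed = 106)
  areas_ca <- ser$tumor_cells
  areas_er <- erosion_area_sequence(tumor_mask(grid),
                                    neighborhood = "vonneumann")
  t_ca <- seq_along(areas_ca) - 1
  t_er <- seq_along(areas_er) - 1
  c_eff <- max(t_er) / max(t_ca)
  expect_gt(c_eff, 0.5)
  expect_lte(c_eff, 1.05)
  peel_at <- stats::approx(t_er, areas_er, xout = pmin(c_eff * t_ca,
                                                       max(t_er)))$y
  expect_lt(max(abs(areas_ca - peel_at)) / areas_ca[1], 0.05)
})

test_that("run_experiment composes the phases deterministically", {
  cfg <- small_cfg(target_size = 400)
  s1 <- run_experiment("spherical", gamma = 2 * pi, seed = 11, config = cfg)
  s2 <- run_experiment("spherical", gamma = 2 * pi, seed = 11, config = cfg)
  expect_identical(s1$tumor_cells, s2$tumor_cells)
  expect_equal(s1$tumor_cells[1], 400, tolerance = 0.02)
  expect_equal(s1$tumor_cells[nrow(s1)], 0)
})

test_that("delta of eroding grown tumors stays in a bounded band", {
  # the shape-deviation factor delta(t) must remain bounded for the
  # erosion of grown tumors of either morphology class
  for (p in c("spherical", "filamentary")) {
    cfg <- morphology_preset(p, n = 151, target_size = 3000)
    grid <- grow_tumor(cfg, seed = 2)
    a <- erosion_area_sequence(tumor_mask(grid))
    dl <- estimate_delta(a[a > 0.02 * a[1]])
    expect_true(all(is.finite(dl)))
    expect_gt(min(dl), 0.4)
    expect_lt(max(dl), 2.5)
  }
})

test_that("3-D ball erosion recovers the surface/volume exponent 2/3", {
  ser <- erode_ball_3d(R0 = 60)
  n <- ser$time_hr
  expect_equal(ser$tumor_cells, (4 / 3) * pi * pmax(0, 60 - n)^3)
  expect_equal(erode_ball_3d(1, 1)$tumor_cells[2], 0)
  fit <- fit_power_law(ser)
  expect_gt(fit$nu, 0.64)
  expect_lt(fit$nu, 0.70)
})

test_that("CA grids round-trip through the text snapshot format", {
  cfg <- small_cfg(target_size = 80)
  grid <- grow_tumor(cfg, seed = 8)
  grid <- place_immune_cells(grid, pi, cfg)
  path <- withr::local_tempfile(fileext = ".txt")
  write_ca_grid(grid, path)
  back <- read_ca_grid(path)
  expect_equal(unclass(back), unclass(unname(grid)),
               ignore_attr = TRUE)
})
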