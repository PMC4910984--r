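#' Cellular automaton configuration
#'
#' Parameters of the two-phase cellular automaton: nutrient-limited
#' avascular growth of a tumor on an `n x n` lattice fed by two vessel
#' columns, followed by frozen-tumor lysis by immune cells. One CA step is
#' one hour; one lattice site is one cell diameter.
#'
#' Action probabilities (the reconstructed rule contract, fixed and
#' documented here):
#' * division: `1 - exp(-(x/theta_div)^2)` with `x` the division nutrient
#'   per competing cell: the concentration at the site, relative to its
#'   healthy-tissue baseline (the field with no tumor present), divided by
#'   the local tumor crowding (1 + tumor cells among the von Neumann
#'   neighbors). The relative concentration makes the drive reflect
#'   tumor-induced depletion rather than distance to the vessels;
#'   (`theta_div = 0` switches division off);
#' * necrosis: `exp(-(x/theta_nec)^2)` with `x` the relative maintenance
#'   nutrient (0 when `theta_nec = 0`);
#' * tumor migration: `1 - exp(-(x/theta_mig)^2)` (0 when
#'   `theta_mig = Inf`);
#' * lysis, recruitment, inactivation: constant drive 1, probability
#'   `1 - exp(-1/theta^2)` each.
#'
#' Larger `theta` always means a less capable action.
#'
#' @param n Grid side (default 300).
#' @param alpha Nutrient consumption factor, per grid unit (default `2/n`).
#' @param lambda_N Division-nutrient consumption rate of tumor cells,
#'   relative to healthy (default 25).
#' @param lambda_M Maintenance-nutrient consumption rate (default 10).
#' @param theta_div Tumor division parameter (default 0.3).
#' @param theta_mig Tumor migration parameter (`Inf` = disabled, default).
#' @param theta_nec Tumor necrosis parameter (0 = disabled, default).
#' @param theta_lys Immune lysis parameter (default 0.3).
#' @param theta_rec Recruitment parameter (default 0.5).
#' @param theta_inc Immune inactivation parameter (default 0.5).
#' @param max_lyses Lyses an immune cell may perform before inactivating
#'   (default 3).
#' @param target_size Tumor size at which growth stops (default 9100).
#' @param nutrient_every Growth sweeps between nutrient re-solves
#'   (default 5).
#' @param immune_migrate Should non-engaged immune cells take random-walk
#'   steps (default TRUE).
#' @param lysis_neighborhood Adjacency for lysis: `"vonneumann"` (default)
#'   or (not implemented in the compiled core) reserved values.
#' @return A `ca_config` list.
#' @export
ca_config <- function(n = 300L, alpha = 2 / n, lambda_N = 25,
                      lambda_M = 10, theta_div = 0.3, theta_mig = Inf,
                      theta_nec = 0, theta_lys = 0.3, theta_rec = 0.5,
                      theta_inc = 0.5, max_lyses = 3L, target_size = 9100L,
                      nutrient_every = 5L, immune_migrate = TRUE,
                      lysis_neighborhood = "vonneumann") {
  n <- as.integer(n)
  stopifnot(n >= 5L, alpha > 0, lambda_N >= 0, lambda_M >= 0,
            theta_div >= 0, theta_mig >= 0, theta_nec >= 0,
            theta_lys > 0, theta_rec > 0, theta_inc > 0,
            max_lyses >= 1L, target_size >= 1L, target_size <= n^2,
            nutrient_every >= 1L)
  structure(list(n = n, alpha = alpha, lambda_N = lambda_N,
                 lambda_M = lambda_M, theta_div = theta_div,
                 theta_mig = theta_mig, theta_nec = theta_nec,
                 theta_lys = theta_lys, theta_rec = theta_rec,
                 theta_inc = theta_inc, max_lyses = as.integer(max_lyses),
                 target_size = as.integer(target_size),
                 nutrient_every = as.integer(nutrient_every),
                 immune_migrate = isTRUE(immune_migrate),
                 lysis_neighborhood = lysis_neighborhood),
            class = "ca_config")
}

#' Morphology presets for the growth phase
#'
#' The three avascular morphologies, controlled by the nutrient
#' consumption parameters on a 300 x 300 grid (all with
#' `theta_div = 0.3`, `lambda_M = 10`, necrosis and migration disabled,
#' grown to ~9100 cells):
#' * `"spherical"`: `alpha = 2/n`, `lambda_N = 25` — weak nutrient
#'   screening, compact round tumor;
#' * `"papillary"`: `alpha = 4/n`, `lambda_N = 200` — intermediate,
#'   lobed boundary;
#' * `"filamentary"`: `alpha = 8/n`, `lambda_N = 270` — strong screening,
#'   branched dendritic tumor.
#'
#' @param preset `"spherical"`, `"papillary"` or `"filamentary"`.
#' @param n Grid side (default 300).
#' @param ... Overrides passed to [ca_config()].
#' @return A `ca_config`.
#' @export
morphology_preset <- function(preset = c("spherical", "papillary",
                                         "filamentary"),
                              n = 300L, ...) {
  preset <- match.arg(preset)
  k <- switch(preset, spherical = 2, papillary = 4, filamentary = 8)
  lam <- switch(preset, spherical = 25, papillary = 200, filamentary = 270)
  cfg <- ca_config(n = n, alpha = k / n, lambda_N = lam, ...)
  cfg$preset <- preset
  cfg
}

new_ca_grid <- function(config) {
  g <- matrix(0L, config$n, config$n)
  structure(g, class = "ca_grid")
}

#' @export
print.ca_grid <- function(x, ...) {
  cat(sprintf("CA grid %d x %d: %d tumor, %d immune cells\n",
              nrow(x), ncol(x), sum(x == 1L), sum(x == 2L)))
  invisible(x)
}

#' Tumor mask of a CA grid
#'
#' @param grid A `ca_grid` (integer matrix; 1 = tumor).
#' @return A [shape_mask] of the tumor cells (spacing 1).
#' @export
tumor_mask <- function(grid) shape_mask(unclass(grid) == 1L, spacing = 1)

#' Steady-state nutrient fields
#'
#' Solves the steady state of the linear reaction-diffusion equations for
#' the division nutrient `N` and the maintenance nutrient `M` on the CA
#' lattice (5-point stencil):
#' \deqn{\nabla^2 u = \alpha^2 \left(1 + (r - 1)\,\mathbf{1}_{tumor}\right) u,}
#' with \eqn{r = \lambda / (1 + \lambda\alpha)} and `lambda = lambda_N`
#' for `N`, `lambda_M` for `M`: every cell consumes, tumor cells `r` times
#' as fast as healthy tissue. The uptake ratio saturates
#' Michaelis-Menten-like in \eqn{\lambda\alpha} — a cell cannot take up
#' nutrient faster than diffusion delivers it through its own membrane —
#' which interpolates between ratio \eqn{\lambda} for small
#' \eqn{\lambda\alpha} and the transport-limited ceiling \eqn{1/\alpha}.
#' Dirichlet condition `u = 1` on the two vessel columns (first and last),
#' periodic in the vertical direction. The discrete operator is an
#' M-matrix, so the fields are non-negative and bounded by 1.
#'
#' @param grid A `ca_grid`.
#' @param config A [ca_config].
#' @param fields Which fields to solve (`"N"`, `"M"` or both).
#' @return List with matrices `N` and/or `M` (unsolved entries `NULL`).
#' @export
solve_nutrients <- function(grid, config, fields = c("N", "M")) {
  stopifnot(inherits(config, "ca_config"))
  tumor <- unclass(grid) == 1L
  a2 <- config$alpha^2
  # tumor-to-healthy uptake ratio saturates Michaelis-Menten-like at 1/alpha:
  # a cell cannot consume more nutrient than diffusion can deliver through
  # its own boundary, so the effective ratio is lambda / (1 + lambda*alpha)
  rN <- config$lambda_N / (1 + config$lambda_N * config$alpha)
  rM <- config$lambda_M / (1 + config$lambda_M * config$alpha)
  out <- list(N = NULL, M = NULL)
  if ("N" %in% fields)
    out$N <- solve_rd_field(a2 * (1 + (rN - 1) * tumor))
  if ("M" %in% fields)
    out$M <- solve_rd_field(a2 * (1 + (rM - 1) * tumor))
  out
}

# Steady-state diffusion with per-site consumption `cons` (n x n matrix),
# Dirichlet u = 1 on columns 1 and n, periodic rows. The stencil pattern
# and the symbolic Cholesky analysis depend only on n, so both are cached;
# each call only refreshes the diagonal and refactorizes numerically.
.rd_cache <- new.env(parent = emptyenv())

rd_structure <- function(n) {
  key <- as.character(n)
  cc <- .rd_cache[[key]]
  if (!is.null(cc)) return(cc)
  m <- n - 2L                      # unknown columns 2..n-1
  idx <- function(i, j) (j - 2L) * n + i
  ii <- rep(seq_len(n), times = m)
  jj <- rep(2:(n - 1L), each = n)
  id <- idx(ii, jj)
  up <- idx(ifelse(ii == 1L, n, ii - 1L), jj)
  dn <- idx(ifelse(ii == n, 1L, ii + 1L), jj)
  left_in <- jj - 1L >= 2L
  right_in <- jj + 1L <= n - 1L
  ti <- c(id, id, id, id[left_in], id[right_in])
  tj <- c(id, up, dn, idx(ii[left_in], jj[left_in] - 1L),
          idx(ii[right_in], jj[right_in] + 1L))
  off_x <- rep(-1, length(ti) - length(id))
  b <- numeric(n * m)
  b[id[!left_in]] <- b[id[!left_in]] + 1    # vessel at column 1
  b[id[!right_in]] <- b[id[!right_in]] + 1  # vessel at column n
  cc <- list(m = m, ti = ti, tj = tj, off_x = off_x, b = b,
             diag_idx = cbind(ii, jj), chol = NULL)
  .rd_cache[[key]] <- cc
  cc
}

solve_rd_field <- function(cons) {
  n <- nrow(cons)
  stopifnot(ncol(cons) == n)
  cc <- rd_structure(n)
  if (is.null(cc$template)) {
    tx <- c(4 + cons[cc$diag_idx], cc$off_x)
    A <- Matrix::sparseMatrix(i = cc$ti, j = cc$tj, x = tx,
                              dims = c(n * cc$m, n * cc$m))
    As <- Matrix::forceSymmetric(A)
    # positions of the diagonal inside the dsCMatrix @x slot, so later
    # calls only overwrite those values instead of reassembling
    p <- As@p
    ncols <- length(p) - 1L
    rows <- As@i
    dpos <- integer(ncols)
    for (col in seq_len(ncols)) {
      kk <- (p[col] + 1L):p[col + 1L]
      dpos[col] <- kk[rows[kk] == col - 1L]
    }
    cc$template <- As
    cc$diag_pos <- dpos
    cc$chol <- Matrix::Cholesky(As)
    .rd_cache[[as.character(n)]] <- cc
    ch <- cc$chol
  } else {
    As <- cc$template
    As@x[cc$diag_pos] <- 4 + cons[cc$diag_idx]
    ch <- Matrix::update(cc$chol, As)
  }
  sol <- Matrix::solve(ch, cc$b)
  u <- matrix(1, n, n)
  u[, 2:(n - 1L)] <- as.numeric(sol)
  if (any(!is.finite(u))) stop("nutrient solve failed", call. = FALSE)
  u
}

#' Grow a tumor from a single seed
#'
#' Phase one of the automaton: a single tumor cell at the grid center
#' divides (and optionally migrates or dies) under the probabilistic rules
#' of [ca_config], with the division-nutrient field re-solved every
#' `nutrient_every` sweeps, until the tumor count first reaches
#' `target_size` (the sweep stops mid-pass, so the overshoot is at most
#' one cell).
#'
#' @param config A [ca_config] (use [morphology_preset()] for the standard
#'   morphologies).
#' @param seed Optional RNG seed (`set.seed`).
#' @return A `ca_grid` with attributes `steps` (growth sweeps used) and
#'   `config`.
#' @export
grow_tumor <- function(config, seed = NULL) {
  stopifnot(inherits(config, "ca_config"))
  if (!is.null(seed)) set.seed(seed)
  grid <- new_ca_grid(config)
  ctr <- as.integer(ceiling(config$n / 2))
  grid[ctr, ctr] <- 1L
  if (config$target_size <= 1L) {
    attr(grid, "steps") <- 0L
    attr(grid, "config") <- config
    return(grid)
  }
  need_M <- config$theta_nec > 0 || is.finite(config$theta_mig)
  # healthy-tissue baseline fields: the division/necrosis drives are the
  # nutrient concentrations relative to this baseline, so the rules see
  # the tumor-induced depletion, not the distance to the vessels
  empty <- new_ca_grid(config)
  base <- solve_nutrients(empty, config,
                          fields = if (need_M) c("N", "M") else "N")
  steps <- 0L
  stall <- 0L
  count <- 1L
  max_steps <- 100L * config$n
  repeat {
    nut <- solve_nutrients(grid, config,
                           fields = if (need_M) c("N", "M") else "N")
    M <- if (need_M) nut$M / base$M else matrix(1, config$n, config$n)
    res <- ca_grow_sweeps(grid, nut$N / base$N, M, config$nutrient_every,
                          config$theta_div, config$theta_nec,
                          config$theta_mig, config$target_size)
    steps <- steps + res$sweeps
    if (res$count >= config$target_size) break
    stall <- if (res$count == count) stall + 1L else 0L
    count <- res$count
    if (stall >= 3L)
      stop(sprintf("tumor growth stalled at %d cells after %d steps",
                   count, steps), call. = FALSE)
    if (steps >= max_steps)
      stop(sprintf("growth did not reach target in %d steps", steps),
           call. = FALSE)
  }
  attr(grid, "steps") <- steps
  attr(grid, "config") <- config
  class(grid) <- "ca_grid"
  grid
}

#' Place immune cells around a grown tumor
#'
#' The tumor is inscribed in its circumscribing circle (centered at the
#' tumor centroid) and every non-tumor site inside that circle whose polar
#' angle from the centroid lies in `[0, gamma)` becomes an immune cell.
#' `gamma = 2*pi` fills the whole remaining disk — the fully-covered limit;
#' small angles leave only a sector engaged, the few-effector limit.
#'
#' @param grid A `ca_grid` with a grown tumor.
#' @param gamma Coverage angle, radians, in `(0, 2*pi]`.
#' @param config A [ca_config].
#' @param margin Extra radius beyond the circumscribing circle, sites
#'   (default 2).
#' @return The grid with immune cells added (attribute `lyscount` reset).
#' @export
place_immune_cells <- function(grid, gamma, config, margin = 2) {
  stopifnot(inherits(config, "ca_config"))
  if (!is.numeric(gamma) || length(gamma) != 1L || gamma <= 0 ||
      gamma > 2 * pi + 1e-12)
    stop("'gamma' must lie in (0, 2*pi]", call. = FALSE)
  g <- unclass(grid)
  tum <- which(g == 1L, arr.ind = TRUE)
  if (nrow(tum) == 0L) stop("no tumor on the grid", call. = FALSE)
  ctr <- colMeans(tum)
  rad <- sqrt(max((tum[, 1] - ctr[1])^2 + (tum[, 2] - ctr[2])^2)) + margin
  n <- nrow(g)
  ii <- matrix(seq_len(n), n, n)
  jj <- t(ii)
  dx <- ii - ctr[1]; dy <- jj - ctr[2]
  inside <- dx^2 + dy^2 <= rad^2 & g == 0L
  inside[, c(1L, n)] <- FALSE              # vessel columns stay cell-free
  ang <- (atan2(dy, dx) + 2 * pi) %% (2 * pi)
  sel <- inside & (ang < gamma | gamma >= 2 * pi - 1e-12)
  g[sel] <- 2L
  structure(g, class = "ca_grid", config = config,
            lyscount = matrix(0L, n, n))
}

#' Run the frozen-tumor lysis phase
#'
#' Phase two: tumor dynamics are frozen (no division, migration or
#' necrosis) and the placed immune cells act each hour — lysing adjacent
#' tumor cells, recruiting on success, inactivating when far from the
#' tumor, and retiring after `max_lyses` kills — until the tumor is
#' eradicated or a step cap of `10 * initial tumor count` is reached.
#'
#' @param grid A `ca_grid` with immune cells placed (see
#'   [place_immune_cells]).
#' @param config A [ca_config].
#' @param seed Optional RNG seed.
#' @param max_steps Step cap (default `10 *` initial tumor count).
#' @return A [lysis_series] with columns `time_hr`, `tumor_cells`,
#'   `immune_cells`; attribute `truncated` is `TRUE` if the cap was hit.
#' @export
run_lysis <- function(grid, config, seed = NULL, max_steps = NULL) {
  stopifnot(inherits(config, "ca_config"))
  if (!is.null(seed)) set.seed(seed)
  g <- unclass(grid)
  storage.mode(g) <- "integer"
  lc <- attr(grid, "lyscount")
  if (is.null(lc)) lc <- matrix(0L, nrow(g), ncol(g))
  n_tumor <- sum(g == 1L)
  if (is.null(max_steps)) max_steps <- max(10L * n_tumor, 100L)
  res <- ca_lysis_run(g, lc, config$theta_lys, config$theta_rec,
                      config$theta_inc, config$max_lyses,
                      as.integer(max_steps), config$immune_migrate)
  lysis_series(seq_along(res$tumor) - 1, res$tumor, res$immune,
               truncated = res$truncated)
}

#' Grow, cover, and lyse: the full two-phase experiment
#'
#' Convenience wrapper reproducing the standard protocol: grow a tumor
#' with a morphology preset to ~9100 cells, place immune cells over an
#' angle `gamma`, and record the lysis until eradication.
#'
#' @param preset Morphology preset name (see [morphology_preset]).
#' @param gamma Coverage angle, radians, in `(0, 2*pi]`.
#' @param seed RNG seed for the whole experiment.
#' @param config Optional [ca_config] to use instead of the preset default
#'   (its `alpha`/`lambda_N` are kept as given).
#' @param ... Overrides passed to [morphology_preset()].
#' @return The [lysis_series] of the decay, with the grown grid attached
#'   as attribute `grid`.
#' @export
run_experiment <- function(preset = "spherical", gamma = 2 * pi,
                           seed = NULL, config = NULL, ...) {
  if (is.null(config)) config <- morphology_preset(preset, ...)
  if (!is.null(seed)) set.seed(seed)
  grid <- grow_tumor(config)
  grid <- place_immune_cells(grid, gamma, config)
  series <- run_lysis(grid, config)
  attr(series, "grid") <- grid
  series
}

#' Constant-speed erosion of a 3-D ball
#'
#' The three-dimensional analogue of layer peeling: a ball of initial
#' radius `R0` loses one unit of radius per step, so the cell count goes
#' as \eqn{V_n = \frac{4}{3}\pi (R_0 - n)^3} until extinction. A power-law
#' fit of this sequence recovers the surface-to-volume exponent
#' `nu = 2/3` expected for compact solid tumors in 3-D.
#'
#' @param R0 Initial radius, cell diameters (> 0).
#' @param steps Number of erosion steps (default: to extinction).
#' @return A [lysis_series] of ball volumes (cells).
#' @export
erode_ball_3d <- function(R0, steps = NULL) {
  stopifnot(R0 > 0)
  if (is.null(steps)) steps <- ceiling(R0)
  n <- 0:steps
  v <- (4 / 3) * pi * pmax(0, R0 - n)^3
  lysis_series(n, v)
}

#' Write a CA grid snapshot as a plain-text coded grid
#'
#' One header line `n n`, then rows of 0/1/2 codes (healthy/tumor/immune).
#'
#' @param grid A `ca_grid`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ca_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d", nrow(grid), ncol(grid)), con)
  utils::write.table(unclass(grid), con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a CA grid snapshot written by [write_ca_grid]
#'
#' @param path Input path.
#' @return A `ca_grid`.
#' @export
read_ca_grid <- function(path) {
  m <- as.matrix(utils::read.table(path, skip = 1))
  dimnames(m) <- NULL
  storage.mode(m) <- "integer"
  structure(m, class = "ca_grid")
}
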