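#' The fractional cell kill K(E, T)
#'
#' Evaluates the saturating kill law
#' \deqn{K(E,T) = \frac{d\,E^\lambda}{s\,T^\nu + E^\lambda}.}
#' `K` is the per-capita lysis rate scale: the tumor decays as
#' \eqn{\dot T = -K(E,T)\,T^\nu}. `K` saturates at `d` for large immune
#' populations, is strictly increasing in `E` (for `T > 0`) and strictly
#' decreasing in `T` (for `E > 0`). With no effectors `K = 0`; the doubly
#' degenerate point `E = T = 0` is a removable singularity also defined
#' as 0.
#'
#' @param params A [kill_params] object.
#' @param E Effector (immune) cell count, >= 0. Vectorized.
#' @param T Tumor cell count, >= 0. Vectorized.
#' @return Kill rate(s), in `[0, d]`.
#' @examples
#' kp <- kill_params(d = 1, lambda = 1, s = 1, nu = 1)
#' fractional_cell_kill(kp, E = 50, T = 50)  # E^lambda = s*T -> d/2
#' @export
fractional_cell_kill <- function(params, E, T) {
  stopifnot(inherits(params, "kill_params"), is.numeric(E), is.numeric(T))
  if (any(!is.finite(E)) || any(!is.finite(T)) || any(E < 0) || any(T < 0))
    stop("populations must be finite and non-negative", call. = FALSE)
  El <- E^params$lambda
  denom <- params$s * T^params$nu + El
  out <- ifelse(E == 0, 0, params$d * El / denom)
  as.numeric(out)
}

#' Right-hand side of the tumor decay ODE
#'
#' Returns \eqn{\dot T = -K(E,T)\,T^\nu = -d E^\lambda T^\nu /
#' (s T^\nu + E^\lambda)}, in cells per hour. Always non-positive, and zero
#' when either population is zero.
#'
#' @inheritParams fractional_cell_kill
#' @return dT/dt, cells/hr (<= 0). Vectorized.
#' @export
decay_rhs <- function(params, E, T) {
  K <- fractional_cell_kill(params, E, T)
  -K * T^params$nu
}

#' Linear-limit decay speed
#'
#' When the tumor is large compared to the immune contingent
#' (\eqn{E_0^\lambda \ll s T^\nu}) the decay speed saturates at the constant
#' \eqn{d E_0^\lambda / s}: the immune cells lyse at their intrinsic pace,
#' independent of tumor size. With `d = s = lambda = 1` and a single
#' effector this is the canonical one tumor cell per hour.
#'
#' @param params A [kill_params] object.
#' @param E0 Effector cell count, >= 0.
#' @return Constant decay speed, cells/hr (>= 0).
#' @export
linear_limit_rate <- function(params, E0) {
  stopifnot(inherits(params, "kill_params"), is.numeric(E0))
  if (any(!is.finite(E0)) || any(E0 < 0))
    stop("'E0' must be finite and non-negative", call. = FALSE)
  params$d * E0^params$lambda / params$s
}

#' Closed-form power-law decay
#'
#' Solution of \eqn{\dot T = -d\,T^\nu} for `0 < nu < 1`:
#' \deqn{T(t) = \max\left(0,\ T_0^{1-\nu} - d(1-\nu)t\right)^{1/(1-\nu)},}
#' which reaches zero exactly at \eqn{t^* = T_0^{1-\nu} / (d(1-\nu))}. The
#' `nu = 1/2` case is the parabolic decay of a disk-shaped tumor eroded in
#' layers at constant radial speed. For `nu = 1` use the exponential form
#' `T0 * exp(-d * t)` instead (this function refuses it).
#'
#' @param d Decay constant, cell^(1-nu)/hr, > 0.
#' @param nu Exponent in (0, 1).
#' @param T0 Initial tumor cell count, >= 0.
#' @param t Time(s), hours. Vectorized.
#' @return Tumor cell count(s) at `t`.
#' @export
closed_form_power_decay <- function(d, nu, T0, t) {
  stopifnot(is.numeric(d), is.numeric(nu), is.numeric(T0), is.numeric(t))
  if (nu >= 1 || nu <= 0)
    stop("'nu' must lie in (0, 1); for nu = 1 use T0 * exp(-d * t)",
         call. = FALSE)
  if (d <= 0) stop("'d' must be positive", call. = FALSE)
  if (T0 < 0) stop("'T0' must be non-negative", call. = FALSE)
  core <- pmax(0, T0^(1 - nu) - d * (1 - nu) * t)
  core^(1 / (1 - nu))
}

#' Extinction time of the power-law decay
#'
#' @inheritParams closed_form_power_decay
#' @return \eqn{t^* = T_0^{1-\nu}/(d(1-\nu))}, hours.
#' @export
power_decay_extinction_time <- function(d, nu, T0) {
  if (nu >= 1 || nu <= 0) stop("'nu' must lie in (0, 1)", call. = FALSE)
  T0^(1 - nu) / (d * (1 - nu))
}

#' Integrate the tumor decay ODE at fixed immune population
#'
#' Numerically integrates \eqn{\dot T = -d E_0^\lambda T^\nu /
#' (s T^\nu + E_0^\lambda)} with the effector population held constant at
#' `E0` (the lysis-phase assumption: immune dynamics are frozen out). Uses
#' classical RK4 with substeps per output interval; once the trajectory
#' crosses zero (which happens in finite time for `nu < 1` in the
#' fully-covered limit) it is clamped at zero.
#'
#' @param params A [kill_params] object.
#' @param T0 Initial tumor cell count, > 0.
#' @param E0 Effector cell count, >= 0 (constant during the decay).
#' @param t_grid Strictly increasing time grid starting at 0, hours.
#' @param substeps RK4 substeps per grid interval (default chosen so the
#'   local step is well below the fastest time scale).
#' @return A [lysis_series] data frame with columns `time_hr`, `tumor_cells`.
#' @export
integrate_decay <- function(params, T0, E0, t_grid, substeps = NULL) {
  stopifnot(inherits(params, "kill_params"))
  if (!is.numeric(T0) || length(T0) != 1L || !is.finite(T0) || T0 <= 0)
    stop("'T0' must be a positive number", call. = FALSE)
  if (!is.numeric(E0) || length(E0) != 1L || !is.finite(E0) || E0 < 0)
    stop("'E0' must be non-negative", call. = FALSE)
  if (!is.numeric(t_grid) || length(t_grid) < 1L || t_grid[1] != 0 ||
      any(diff(t_grid) <= 0))
    stop("'t_grid' must be strictly increasing and start at 0", call. = FALSE)

  if (E0 == 0)
    return(lysis_series(t_grid, rep(T0, length(t_grid))))

  # fastest local rate: |dT/dt| <= linear speed and <= d * T0^nu
  if (is.null(substeps)) {
    dt_max <- max(diff(t_grid))
    rate <- min(linear_limit_rate(params, E0), params$d * T0^params$nu)
    substeps <- max(20L, ceiling(4 * dt_max * rate / max(T0 * 1e-3, 1)))
  }

  rhs <- function(T) {
    if (T <= 0) return(0)
    El <- E0^params$lambda
    Tn <- T^params$nu
    -params$d * El * Tn / (params$s * Tn + El)
  }

  out <- numeric(length(t_grid))
  out[1] <- T0
  T <- T0
  for (i in seq_along(t_grid)[-1]) {
    h <- (t_grid[i] - t_grid[i - 1]) / substeps
    for (k in seq_len(substeps)) {
      if (T <= 0) { T <- 0; break }
      k1 <- rhs(T)
      k2 <- rhs(max(0, T + h / 2 * k1))
      k3 <- rhs(max(0, T + h / 2 * k2))
      k4 <- rhs(max(0, T + h * k3))
      T <- T + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
      if (!is.finite(T)) stop("decay integration failed (non-finite state)",
                              call. = FALSE)
      if (T < 0) T <- 0
    }
    out[i] <- T
  }
  lysis_series(t_grid, out)
}
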