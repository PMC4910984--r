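#' Area sequence of a disk eroded layer by layer
#'
#' A disk-shaped tumor plainly covered by immune cells loses one cell layer
#' per step: \eqn{R_{n+1} = R_n - \Delta R}. Substituting \eqn{A = \pi R^2}
#' gives the area map
#' \deqn{A_{n+1} = A_n + \pi \Delta R^2 - 2\pi^{1/2}\Delta R\,A_n^{1/2},}
#' evaluated here by direct iteration. The `n`-th element equals
#' \eqn{\pi (R_0 - n\Delta R)^2} exactly (an algebraic identity), clamped at
#' zero once the radius is exhausted.
#'
#' @param R0 Initial radius, cell diameters (> 0).
#' @param dR Radius lost per step, cell diameters (> 0).
#' @param n_steps Number of erosion steps (>= 0).
#' @return Numeric vector of `n_steps + 1` areas, element 1 being the
#'   initial area \eqn{\pi R_0^2}.
#' @export
disk_area_map <- function(R0, dR, n_steps) {
  stopifnot(is.numeric(R0), R0 > 0, is.numeric(dR), dR > 0,
            is.numeric(n_steps), n_steps >= 0)
  n_steps <- as.integer(n_steps)
  A <- numeric(n_steps + 1L)
  A[1] <- pi * R0^2
  for (n in seq_len(n_steps)) {
    prev <- A[n]
    if (prev <= 0 || sqrt(prev / pi) <= dR) {
      A[n + 1L] <- 0
    } else {
      A[n + 1L] <- prev + pi * dR^2 - 2 * sqrt(pi) * dR * sqrt(prev)
    }
  }
  pmax(A, 0)
}

#' Continuum erosion rate of a disk
#'
#' For a disk whose radius shrinks at constant speed `c`,
#' \deqn{\frac{dA}{dt} = 2\pi R \dot R = -2\pi^{1/2} c\,A^{1/2}.}
#' The implied decay constant of the parabolic law \eqn{\dot T = -dT^{1/2}}
#' is \eqn{d = 2\pi^{1/2} c}.
#'
#' @param A Area(s), >= 0.
#' @param c Radial erosion speed, cell diameters/hr (> 0).
#' @return dA/dt (<= 0). Vectorized in `A`.
#' @export
disk_continuum_rate <- function(A, c) {
  stopifnot(is.numeric(A), is.numeric(c), c > 0)
  if (any(A < 0)) stop("'A' must be non-negative", call. = FALSE)
  -2 * sqrt(pi) * c * sqrt(A)
}

#' Decay constant of the parabolic law for radial speed c
#'
#' @param c Radial erosion speed, cell diameters/hr.
#' @return `2 * sqrt(pi) * c`.
#' @export
disk_decay_constant <- function(c) 2 * sqrt(pi) * c

#' Area erosion rate of an ellipse
#'
#' For an ellipse whose semi-axes both shrink at speed `c`
#' (\eqn{\dot a = \dot b = -c}), the area \eqn{A = \pi a b} obeys
#' \deqn{\frac{dA}{dt} = -\pi^{1/2} c\left[(1-e^2)^{1/4} +
#'   (1-e^2)^{-1/4}\right] A^{1/2},}
#' with eccentricity \eqn{e = \sqrt{1 - b^2/a^2}}. At `e = 0` the bracket
#' equals 2 and the disk rate is recovered; for `e > 0` it exceeds 2
#' (AM-GM), so elongated shapes lose area faster relative to
#' \eqn{A^{1/2}} — the source of the bounded \eqn{\delta(t)} correction for
#' non-circular tumors.
#'
#' @param a Semi-major axis (>= b).
#' @param b Semi-minor axis (> 0).
#' @param c Axis erosion speed (> 0).
#' @return `dA/dt` (< 0).
#' @export
ellipse_area_rate <- function(a, b, c) {
  stopifnot(is.numeric(a), is.numeric(b), is.numeric(c), c > 0)
  if (b <= 0 || a < b)
    stop("need a >= b > 0 (degenerate ellipse e -> 1 not allowed)",
         call. = FALSE)
  e2 <- 1 - b^2 / a^2
  A <- pi * a * b
  -sqrt(pi) * c * ellipse_bracket_factor(sqrt(e2)) * sqrt(A)
}

#' The eccentricity bracket factor of the ellipse erosion rate
#'
#' Returns \eqn{(1-e^2)^{1/4} + (1-e^2)^{-1/4}}, which is >= 2 for all
#' `e` in `[0, 1)` with equality iff `e = 0`.
#'
#' @param e Eccentricity in `[0, 1)`. Vectorized.
#' @return Bracket factor(s).
#' @export
ellipse_bracket_factor <- function(e) {
  stopifnot(is.numeric(e))
  if (any(e < 0 | e >= 1))
    stop("'e' must lie in [0, 1)", call. = FALSE)
  q <- (1 - e^2)^(1 / 4)
  q + 1 / q
}

#' Shape-deviation factor delta(t) from an area sequence
#'
#' An arbitrary eroding tumor is represented as a sequence of equivalent
#' disks \eqn{R_n = \sqrt{A_n/\pi}}. The per-step radius drop, in units of
#' the nominal drop \eqn{\Delta R = c\,\Delta t}, is
#' \deqn{\delta_n = \frac{R_n - R_{n+1}}{\Delta R}.}
#' For an exact disk erosion \eqn{\delta \equiv 1}; two equal disks eroding
#' in sync give \eqn{\delta = \sqrt 2}; bounded deviations keep the
#' parabolic law a good description (\eqn{\dot T = -d(t) T^{1/2}} with
#' \eqn{d(t) = 2\pi^{1/2} c\,\delta(t)}).
#'
#' @param areas Positive, non-increasing area sequence (physical units).
#' @param c Radial erosion speed per step interval (default 1: one cell
#'   diameter per step).
#' @param dt Step interval, hours (default 1).
#' @return Numeric vector of `length(areas) - 1` delta values.
#' @export
estimate_delta <- function(areas, c = 1, dt = 1) {
  stopifnot(is.numeric(areas), length(areas) >= 2L, c > 0, dt > 0)
  if (any(areas < 0)) stop("areas must be non-negative", call. = FALSE)
  if (any(diff(areas) > 1e-9 * max(areas)))
    stop("areas must be non-increasing", call. = FALSE)
  R <- sqrt(areas / pi)
  (R[-length(R)] - R[-1]) / (c * dt)
}
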