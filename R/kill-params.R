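#' Kinetic parameter set for the fractional cell kill law
#'
#' Bundles the four parameters of the saturating kill law
#' \deqn{K(E,T) = \frac{d\,E^\lambda}{s\,T^\nu + E^\lambda},}
#' the per-capita rate at which effector (cytotoxic immune) cells lyse a
#' tumor. `d` is the maximal fractional kill, `lambda` and `nu` are the
#' geometry-driven Hill exponents for the immune and tumor populations, and
#' `s` scales the intrinsic effectiveness of the effector cells (larger `s`
#' means less effective cells). The classical saturating law with a linear
#' tumor term is the special case `nu = 1`.
#'
#' @param d Maximal fractional kill rate. Units cell^(1-nu)/hr (1/hr when
#'   `nu = 1`). Must be positive.
#' @param lambda Immune-population exponent, in (0, 1]. Dimensionless.
#' @param s Immune-effectiveness constant, > 0. Dimensionless scale; larger
#'   values describe less effective effector cells.
#' @param nu Tumor-population exponent, in (0, 1]. Dimensionless; 1/2 for
#'   two-dimensional layer-by-layer erosion, 2/3 for compact 3-D tumors,
#'   1 for well-mixed (infiltrated or non-solid) tumors.
#'
#' @return An object of class `kill_params`.
#' @examples
#' kp <- kill_params(d = 1, lambda = 1, s = 1, nu = 1)
#' fractional_cell_kill(kp, E = 50, T = 50)  # half-maximum: 0.5
#' @export
kill_params <- function(d, lambda = 1, s = 1, nu = 1) {
  stopifnot(is.numeric(d), is.numeric(lambda), is.numeric(s), is.numeric(nu),
            length(d) == 1L, length(lambda) == 1L, length(s) == 1L,
            length(nu) == 1L)
  if (!is.finite(d) || d <= 0)
    stop("'d' must be a positive finite number", call. = FALSE)
  if (!is.finite(lambda) || lambda <= 0 || lambda > 1)
    stop("'lambda' must lie in (0, 1]", call. = FALSE)
  if (!is.finite(s) || s <= 0)
    stop("'s' must be positive", call. = FALSE)
  if (!is.finite(nu) || nu <= 0 || nu > 1)
    stop("'nu' must lie in (0, 1]", call. = FALSE)
  structure(list(d = d, lambda = lambda, s = s, nu = nu),
            class = "kill_params")
}

#' @export
print.kill_params <- function(x, ...) {
  cat("Fractional cell kill parameters\n")
  cat(sprintf("  d      = %g  (max kill rate, cell^(1-nu)/hr)\n", x$d))
  cat(sprintf("  lambda = %g  (immune exponent)\n", x$lambda))
  cat(sprintf("  s      = %g  (effectiveness constant)\n", x$s))
  cat(sprintf("  nu     = %g  (tumor exponent)\n", x$nu))
  invisible(x)
}

#' Rescale the effectiveness constant for a partially engaged immune pool
#'
#' When only a fraction `f` of the effector population actually engages the
#' tumor, replacing `E` by `f * E` in the kill law is equivalent to keeping
#' `E` and replacing `s` by `s / f^lambda`. This returns the rescaled
#' parameter set, so that
#' `fractional_cell_kill(rescaled, E, T) == fractional_cell_kill(original, f * E, T)`
#' for every state.
#'
#' @param params A [kill_params] object.
#' @param f Engaged fraction of the immune population, in (0, 1].
#' @return A [kill_params] object with `s` replaced by `s / f^lambda`.
#' @export
effectiveness_rescale <- function(params, f) {
  stopifnot(inherits(params, "kill_params"), is.numeric(f), length(f) == 1L)
  if (!is.finite(f) || f <= 0 || f > 1)
    stop("'f' must lie in (0, 1]", call. = FALSE)
  kill_params(d = params$d, lambda = params$lambda,
              s = params$s / f^params$lambda, nu = params$nu)
}

#' Read kill-law parameters from a flat JSON mapping
#'
#' Expects a JSON object with fields `d`, `lambda`, `s`, `nu` (missing
#' `lambda`, `s`, `nu` default to 1).
#'
#' @param path Path to a JSON file.
#' @return A [kill_params] object.
#' @export
read_kill_params <- function(path) {
  x <- jsonlite::fromJSON(path)
  if (is.null(x$d)) stop("JSON mapping must contain field 'd'", call. = FALSE)
  kill_params(d = x$d,
              lambda = if (is.null(x$lambda)) 1 else x$lambda,
              s = if (is.null(x$s)) 1 else x$s,
              nu = if (is.null(x$nu)) 1 else x$nu)
}

#' Write kill-law parameters to JSON
#'
#' @param params A [kill_params] object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kill_params <- function(params, path) {
  stopifnot(inherits(params, "kill_params"))
  jsonlite::write_json(list(d = params$d, lambda = params$lambda,
                            s = params$s, nu = params$nu),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
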