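#' Single-lymphocyte random-walk lysis
#'
#' The linear-decay limit made literal: one cytotoxic lymphocyte performs
#' an unbiased random walk on a square domain fully occupied by tumor
#' cells, starting at the bottom-left corner. Each hour it lyses the tumor
#' cell at its current site if one is present (at most one lysis per hour),
#' then moves to a uniformly random 4-neighbor site, reflecting at the
#' domain walls. Revisiting an already-lysed site wastes the hour unless
#' `skip_lysed = TRUE`, in which case the move is redrawn among sites until
#' a fresh one (if any neighbor is fresh) — the paper-silent choice is
#' exposed as a flag, with "wastes the hour" the default.
#'
#' The decay is 1-Lipschitz (at most one cell per hour): the literal
#' "one tumor cell per hour" linear bound for a single effector.
#'
#' @param side Domain side, cells (>= 1).
#' @param hours Number of hours to simulate (>= 0).
#' @param seed Optional RNG seed (`set.seed`).
#' @param skip_lysed If `TRUE`, prefer moves onto unlysed neighbor sites.
#' @return A list with `series` (a [lysis_series]) and `path`
#'   (an `(hours + 1) x 2` matrix of lattice positions).
#' @export
run_walker <- function(side, hours, seed = NULL, skip_lysed = FALSE) {
  stopifnot(side >= 1, hours >= 0)
  if (!is.null(seed)) set.seed(seed)
  side <- as.integer(side); hours <- as.integer(hours)
  occupied <- matrix(TRUE, side, side)
  pos <- c(1L, 1L)
  path <- matrix(NA_integer_, hours + 1L, 2L,
                 dimnames = list(NULL, c("x", "y")))
  path[1L, ] <- pos
  count <- numeric(hours + 1L)
  count[1L] <- side^2
  n <- side^2
  moves <- rbind(c(1L, 0L), c(-1L, 0L), c(0L, 1L), c(0L, -1L))
  for (h in seq_len(hours)) {
    if (occupied[pos[1L], pos[2L]]) {
      occupied[pos[1L], pos[2L]] <- FALSE
      n <- n - 1L
    }
    cand <- sweep(moves, 2L, pos, `+`)
    ok <- cand[, 1L] >= 1L & cand[, 1L] <= side &
      cand[, 2L] >= 1L & cand[, 2L] <= side
    cand <- cand[ok, , drop = FALSE]
    if (skip_lysed) {
      fresh <- occupied[cbind(cand[, 1L], cand[, 2L])]
      if (any(fresh)) cand <- cand[fresh, , drop = FALSE]
    }
    # a 1x1 domain has no neighbor to move to: stay put
    if (nrow(cand) > 0L) pos <- cand[sample.int(nrow(cand), 1L), ]
    path[h + 1L, ] <- pos
    count[h + 1L] <- n
  }
  list(series = lysis_series(0:hours, count), path = path)
}
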