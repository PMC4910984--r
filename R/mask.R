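#' Binary shape mask on a square lattice
#'
#' A rasterized tumor shape: a 0/1 integer matrix (1 = occupied by tumor)
#' with a lattice spacing in cell diameters per pixel. The stand-in for
#' tumors of arbitrary geometry whose erosion the analytic disk/ellipse
#' formulas only approximate.
#'
#' @param m Numeric/logical matrix; nonzero entries are occupied.
#' @param spacing Lattice spacing, cell diameters per pixel (> 0).
#' @return An object of class `shape_mask` (integer matrix with a
#'   `spacing` attribute).
#' @export
shape_mask <- function(m, spacing = 1) {
  stopifnot(is.matrix(m), spacing > 0)
  m <- matrix(as.integer(m != 0), nrow(m), ncol(m))
  if (sum(m) == 0L) stop("mask must contain at least one occupied pixel",
                         call. = FALSE)
  structure(m, spacing = spacing, class = "shape_mask")
}

#' @export
print.shape_mask <- function(x, ...) {
  cat(sprintf("Shape mask %d x %d, %d occupied pixels, area %g\n",
              nrow(x), ncol(x), sum(x), mask_area(x)))
  invisible(x)
}

#' Area of a shape mask
#'
#' Occupied pixel count times spacing squared.
#' @param mask A [shape_mask].
#' @return Area, cell diameters squared.
#' @export
mask_area <- function(mask) {
  stopifnot(inherits(mask, "shape_mask"))
  sum(mask) * attr(mask, "spacing")^2
}

#' Perimeter of a shape mask
#'
#' Counts exposed pixel edges (4-neighborhood) times spacing.
#' @param mask A [shape_mask].
#' @return Perimeter, cell diameters.
#' @export
mask_perimeter <- function(mask) {
  stopifnot(inherits(mask, "shape_mask"))
  m <- pad_mask(mask)
  nr <- nrow(m); nc <- ncol(m)
  core <- m[2:(nr - 1), 2:(nc - 1)]
  exposed <- (core & !m[1:(nr - 2), 2:(nc - 1)]) +
    (core & !m[3:nr, 2:(nc - 1)]) +
    (core & !m[2:(nr - 1), 1:(nc - 2)]) +
    (core & !m[2:(nr - 1), 3:nc])
  sum(exposed) * attr(mask, "spacing")
}

#' Isoperimetric ratio of a shape mask
#'
#' \eqn{4\pi A / P^2}: 1 for a perfect disk, smaller for elongated or
#' branched shapes. Used to order tumor morphologies (spherical >
#' papillary > filamentary). Pixelation biases the raster value below the
#' continuum one (a rasterized disk's 4-neighbor perimeter exceeds
#' \eqn{2\pi R}), so compare like with like.
#'
#' @param mask A [shape_mask].
#' @return The ratio (dimensionless).
#' @export
isoperimetric_ratio <- function(mask) {
  4 * pi * mask_area(mask) / mask_perimeter(mask)^2
}

pad_mask <- function(mask) {
  m <- unclass(mask)
  out <- matrix(0L, nrow(m) + 2L, ncol(m) + 2L)
  out[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)] <- m
  out
}

boundary_pixels <- function(m, neighborhood) {
  nr <- nrow(m); nc <- ncol(m)
  p <- matrix(0L, nr + 2L, nc + 2L)
  p[2:(nr + 1L), 2:(nc + 1L)] <- m
  i <- 2:(nr + 1L); j <- 2:(nc + 1L)
  free_n <- (!p[i - 1L, j]) + (!p[i + 1L, j]) +
    (!p[i, j - 1L]) + (!p[i, j + 1L])
  if (neighborhood == "moore") {
    free_n <- free_n + (!p[i - 1L, j - 1L]) + (!p[i - 1L, j + 1L]) +
      (!p[i + 1L, j - 1L]) + (!p[i + 1L, j + 1L])
  }
  (m == 1L) & (free_n > 0L)
}

#' Erode a shape mask layer by layer
#'
#' Removes one layer of unit thickness per step — the discrete realization
#' of the immune system erasing one tumor layer per hour at unit radial
#' speed. Under the default `"euclidean"` neighborhood the mask after `n`
#' steps keeps exactly the pixels whose Euclidean distance to the
#' unoccupied background exceeds `n` (computed once by an exact distance
#' transform), which is the Minkowski erosion by a disk of radius `n`: a
#' rasterized disk then reproduces the continuum area law
#' \eqn{\pi (R_0 - n)^2} up to pixelation. The `"moore"` and
#' `"vonneumann"` modes instead peel, per step, the occupied pixels with
#' at least one unoccupied lattice neighbor; they are the right
#' comparators for lattice processes (the cellular automaton lyses through
#' von Neumann contact) but over- respectively under-shoot the continuum
#' radial speed anisotropically, so the eroding shape slowly
#' polygonalizes.
#'
#' @param mask A [shape_mask].
#' @param layers Number of erosion steps (>= 0).
#' @param neighborhood `"euclidean"` (default), `"moore"` (8-neighbor
#'   peel) or `"vonneumann"` (4-neighbor peel).
#' @return List of `layers + 1` masks (the first is the input); once a mask
#'   is empty, erosion stops and the list is shortened (an empty mask is
#'   represented as the all-zero matrix of class `shape_mask_empty`).
#' @export
erode_mask <- function(mask, layers,
                       neighborhood = c("euclidean", "moore", "vonneumann")) {
  stopifnot(inherits(mask, "shape_mask"), layers >= 0)
  neighborhood <- match.arg(neighborhood)
  spacing <- attr(mask, "spacing")
  out <- vector("list", layers + 1L)
  out[[1L]] <- mask
  m <- unclass(mask)
  if (neighborhood == "euclidean") {
    D <- distance_to_background(m)
    # quarter-pixel threshold offset: center-to-center distances along the
    # lattice axes are exact integers, so integer thresholds would tie
    # with whole distance shells; D^2 is integer, hence D never equals
    # k + 1/4 and the cut is tie-free
    for (k in seq_len(layers)) {
      m2 <- matrix(as.integer(D > k + 0.25), nrow(m), ncol(m))
      if (sum(m2) == 0L) {
        out[[k + 1L]] <- structure(m2, spacing = spacing,
                                   class = "shape_mask_empty")
        return(out[seq_len(k + 1L)])
      }
      out[[k + 1L]] <- structure(m2, spacing = spacing,
                                 class = "shape_mask")
    }
    return(out)
  }
  for (k in seq_len(layers)) {
    b <- boundary_pixels(m, neighborhood)
    m <- m * (1L - b * 1L)
    if (sum(m) == 0L) {
      out[[k + 1L]] <- structure(m, spacing = spacing,
                                 class = "shape_mask_empty")
      return(out[seq_len(k + 1L)])
    }
    out[[k + 1L]] <- structure(m, spacing = spacing, class = "shape_mask")
  }
  out
}

# Exact Euclidean distance from each occupied pixel to the nearest
# unoccupied pixel (pixels outside the matrix count as unoccupied), via
# the two-pass separable squared-distance transform.
distance_to_background <- function(m) {
  big <- (nrow(m) + ncol(m) + 2)^2
  f <- ifelse(m == 1L, big, 0)
  # pad with background so the mask edge is eroded too
  f <- rbind(0, cbind(0, f, 0), 0)
  g <- apply(f, 2L, dt_squared_1d)
  D2 <- t(apply(g, 1L, dt_squared_1d))
  sqrt(D2[2:(nrow(m) + 1L), 2:(ncol(m) + 1L)])
}

# 1-D squared distance transform (lower envelope of parabolas).
dt_squared_1d <- function(f) {
  n <- length(f)
  d <- numeric(n)
  v <- integer(n)
  z <- numeric(n + 1L)
  k <- 1L
  v[1L] <- 1L
  z[1L] <- -Inf
  z[2L] <- Inf
  for (q in 2:n) {
    repeat {
      s <- ((f[q] + q^2) - (f[v[k]] + v[k]^2)) / (2 * q - 2 * v[k])
      if (k > 1L && s <= z[k]) k <- k - 1L else break
    }
    k <- k + 1L
    v[k] <- q
    z[k] <- s
    z[k + 1L] <- Inf
  }
  k <- 1L
  for (q in 1:n) {
    while (z[k + 1L] < q) k <- k + 1L
    d[q] <- (q - v[k])^2 + f[v[k]]
  }
  d
}

#' Area sequence of a mask erosion
#'
#' Convenience: [erode_mask] until empty (or `max_layers`), returning the
#' per-step areas.
#'
#' @param mask A [shape_mask].
#' @param max_layers Cap on the number of layers (default: enough to
#'   guarantee extinction).
#' @inheritParams erode_mask
#' @return Numeric vector of areas, first element the initial area, last
#'   element 0 if extinction was reached.
#' @export
erosion_area_sequence <- function(mask, max_layers = NULL,
                                  neighborhood = c("euclidean", "moore",
                                                   "vonneumann")) {
  neighborhood <- match.arg(neighborhood)
  if (is.null(max_layers)) max_layers <- max(dim(mask))
  seqs <- erode_mask(mask, max_layers, neighborhood)
  vapply(seqs, function(m) sum(unclass(m)) * attr(m, "spacing")^2, numeric(1))
}

#' Rasterize a disk onto a lattice
#'
#' @param R Radius in pixels (> 0).
#' @param spacing Lattice spacing, cell diameters per pixel.
#' @param centers Optional k x 2 matrix of centers (pixels); default one
#'   disk centered in a square just large enough.
#' @return A [shape_mask].
#' @export
rasterize_disk <- function(R, spacing = 1, centers = NULL) {
  stopifnot(R > 0)
  if (is.null(centers)) {
    n <- as.integer(2 * ceiling(R) + 3)
    centers <- matrix((n + 1) / 2, 1, 2)
  } else {
    centers <- as.matrix(centers)
    n <- as.integer(ceiling(max(centers) + R + 2))
  }
  xs <- matrix(seq_len(n), n, n)
  ys <- t(xs)
  m <- matrix(0L, n, n)
  for (k in seq_len(nrow(centers))) {
    m <- m | ((xs - centers[k, 1])^2 + (ys - centers[k, 2])^2 <= R^2)
  }
  shape_mask(m * 1L, spacing)
}

#' Write a shape mask as a plain-text 0/1 grid
#'
#' PGM-style header line `rows cols spacing`, then one row of
#' space-separated 0/1 per lattice row.
#'
#' @param mask A [shape_mask].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_shape_mask <- function(mask, path) {
  stopifnot(inherits(mask, "shape_mask"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d %g", nrow(mask), ncol(mask),
                     attr(mask, "spacing")), con)
  utils::write.table(unclass(mask), con, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a shape mask written by [write_shape_mask]
#'
#' @param path Input path.
#' @return A [shape_mask].
#' @export
read_shape_mask <- function(path) {
  hdr <- scan(path, nlines = 1, quiet = TRUE)
  m <- as.matrix(utils::read.table(path, skip = 1))
  dimnames(m) <- NULL
  stopifnot(nrow(m) == hdr[1], ncol(m) == hdr[2])
  shape_mask(m, spacing = hdr[3])
}
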