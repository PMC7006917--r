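#' Rectangular membrane patch (region of interest)
#'
#' The simulation domain is a flat rectangle with toroidally wrapped (periodic)
#' boundaries, so the patch has no edges and the number of molecules is
#' conserved. All lengths are in nanometres. The default 3000 x 3000 nm patch
#' is the standard region of interest used throughout the package.
#'
#' @param width,height Box dimensions in nm. `height` defaults to `width`.
#' @return An object of class `roi_box` with fields `width` and `height`.
#' @examples
#' b <- roi_box(3000)
#' box_area(b) # 9e6 nm^2
#' @export
roi_box <- function(width = 3000, height = width) {
  stopifnot(is.numeric(width), length(width) == 1L, is.finite(width), width > 0,
            is.numeric(height), length(height) == 1L, is.finite(height), height > 0)
  structure(list(width = as.numeric(width), height = as.numeric(height)),
            class = "roi_box")
}

#' @rdname roi_box
#' @param box An `roi_box`.
#' @export
box_area <- function(box) {
  stopifnot(inherits(box, "roi_box"))
  box$width * box$height
}

#' @export
print.roi_box <- function(x, ...) {
  cat(sprintf("<roi_box> %g x %g nm (toroidal)\n", x$width, x$height))
  invisible(x)
}

#' Spatial point pattern on a toroidal box
#'
#' Positions of molecules at one frame. Coordinates live on the half-open
#' intervals `[0, width)` and `[0, height)` so every point has a unique
#' wrapped representative.
#'
#' @param x,y Numeric coordinate vectors in nm, equal length.
#' @param box An [roi_box()].
#' @return An object of class `point_pattern` with fields `x`, `y`, `box`.
#' @export
point_pattern <- function(x, y, box) {
  stopifnot(inherits(box, "roi_box"), is.numeric(x), is.numeric(y),
            length(x) == length(y))
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) && (any(!is.finite(x)) || any(!is.finite(y))))
    stop("coordinates must be finite")
  if (length(x) && (any(x < 0) || any(x >= box$width) ||
                    any(y < 0) || any(y >= box$height)))
    stop("coordinates must lie in [0, width) x [0, height); use wrap_torus()")
  structure(list(x = x, y = y, box = box), class = "point_pattern")
}

#' @rdname point_pattern
#' @param pattern A `point_pattern`.
#' @export
n_points <- function(pattern) {
  stopifnot(inherits(pattern, "point_pattern"))
  length(pattern$x)
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("<point_pattern> %d molecules on a %g x %g nm torus\n",
              length(x$x), x$box$width, x$box$height))
  invisible(x)
}

# coerce a length-2 vector or an n x 2 matrix to an n x 2 matrix
as_xy <- function(p) {
  if (is.matrix(p)) {
    stopifnot(ncol(p) == 2L)
    return(p)
  }
  stopifnot(is.numeric(p), length(p) == 2L)
  matrix(p, ncol = 2L)
}

#' Minimum-image displacement and distance on the torus
#'
#' `toroidal_displacement(p, q, box)` returns the shortest vector from `p` to
#' `q` under periodic boundary conditions; each component has magnitude at
#' most half the corresponding box dimension. `toroidal_distance()` is its
#' Euclidean norm.
#'
#' @param p,q Points: length-2 vectors `(x, y)` or n x 2 matrices (rows are
#'   points), in nm, inside the box.
#' @param box An [roi_box()].
#' @return For matrix input an n x 2 matrix (or length-n vector of distances);
#'   for two single points a length-2 vector (or scalar distance).
#' @examples
#' b <- roi_box(3000)
#' toroidal_displacement(c(1, 500), c(2999, 500), b) # c(-2, 0): across the seam
#' @export
toroidal_displacement <- function(p, q, box) {
  stopifnot(inherits(box, "roi_box"))
  pm <- as_xy(p); qm <- as_xy(q)
  if (nrow(pm) == 1L && nrow(qm) > 1L) pm <- pm[rep(1L, nrow(qm)), , drop = FALSE]
  if (nrow(qm) == 1L && nrow(pm) > 1L) qm <- qm[rep(1L, nrow(pm)), , drop = FALSE]
  stopifnot(nrow(pm) == nrow(qm))
  dims <- c(box$width, box$height)
  for (j in 1:2) {
    if (any(pm[, j] < 0 | pm[, j] >= dims[j] | qm[, j] < 0 | qm[, j] >= dims[j]))
      stop("points must lie inside the box")
  }
  d <- qm - pm
  d[, 1] <- d[, 1] - dims[1] * round(d[, 1] / dims[1])
  d[, 2] <- d[, 2] - dims[2] * round(d[, 2] / dims[2])
  if (!is.matrix(p) && !is.matrix(q) && nrow(d) == 1L) return(drop(d))
  d
}

#' @rdname toroidal_displacement
#' @export
toroidal_distance <- function(p, q, box) {
  d <- toroidal_displacement(p, q, box)
  if (is.matrix(d)) sqrt(rowSums(d^2)) else sqrt(sum(d^2))
}

#' Wrap positions back onto the torus
#'
#' Reduces each coordinate modulo the box dimension into `[0, width)` /
#' `[0, height)`. Idempotent; agent count is conserved by construction.
#'
#' @param p A length-2 vector or n x 2 matrix of positions in nm.
#' @param box An [roi_box()].
#' @return Positions of the same shape as `p`, inside the box.
#' @examples
#' wrap_torus(c(3005, -3), roi_box(3000)) # c(5, 2997)
#' @export
wrap_torus <- function(p, box) {
  stopifnot(inherits(box, "roi_box"))
  pm <- as_xy(p)
  pm[, 1] <- pm[, 1] %% box$width
  pm[, 2] <- pm[, 2] %% box$height
  # `%%` can return the modulus itself when the remainder underflows
  pm[, 1][pm[, 1] >= box$width] <- 0
  pm[, 2][pm[, 2] >= box$height] <- 0
  if (!is.matrix(p)) return(drop(pm))
  pm
}
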