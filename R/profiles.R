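#' Displacement-versus-density profile ("desire for clustering")
#'
#' The single behavioural rule of the model: each agent's per-millisecond
#' displacement is a decreasing function of its current localized L value, so
#' agents slow down as their neighbourhood approaches a target density.
#' Four families are supported:
#'
#' * `linear_converging` — the Standard Condition: displacement decreases
#'   linearly from `d_max` (at `l_anchor`) to zero at `l_target`; any agent
#'   at or above the target is fully immobile.
#' * `linear_floor` — as above but floored at `d_min > 0`, so agents keep a
#'   residual mobility even at the target.
#' * `tent_nonconverging` — displacement is zero only at exactly
#'   `l_target` and rises linearly on both sides (clamped at `d_max`).
#' * `quadratic` — the linear converging ramp squared, giving a softer
#'   approach to the target (rate at the half-way L is `d_max/4`).
#'
#' @param family Profile family, see above.
#' @param d_max Maximum displacement rate in nm/ms (e.g. 3.5 in the Standard
#'   Condition, i.e. a 35 nm step per 10 ms frame).
#' @param l_target Target localized L in nm (> `l_anchor`). Use
#'   [l_from_count()] to express a target given as a neighbour count.
#' @param d_min Minimum displacement rate in nm/ms (only used by
#'   `linear_floor`); `0 <= d_min <= d_max`.
#' @param l_anchor L value at which the rate equals `d_max`; default 0, so
#'   the ramp spans the whole range from an empty neighbourhood to the target.
#' @return An object of class `displacement_profile`.
#' @examples
#' pr <- displacement_profile("linear_converging", d_max = 3.5,
#'                            l_target = l_from_count(45, 2000, 9e6))
#' displacement_rate(pr, c(0, 100, 250, 400))
#' @export
displacement_profile <- function(family = c("linear_converging", "linear_floor",
                                            "tent_nonconverging", "quadratic"),
                                 d_max, l_target, d_min = 0, l_anchor = 0) {
  family <- match.arg(family)
  stopifnot(is.numeric(d_max), length(d_max) == 1L, is.finite(d_max), d_max >= 0,
            is.numeric(d_min), length(d_min) == 1L, is.finite(d_min), d_min >= 0,
            is.numeric(l_target), length(l_target) == 1L, is.finite(l_target),
            is.numeric(l_anchor), length(l_anchor) == 1L, l_anchor >= 0)
  if (d_min > d_max) stop("d_min must not exceed d_max")
  if (l_target <= l_anchor) stop("l_target must exceed l_anchor")
  structure(list(family = family, d_max = as.numeric(d_max),
                 d_min = as.numeric(d_min), l_target = as.numeric(l_target),
                 l_anchor = as.numeric(l_anchor)),
            class = "displacement_profile")
}

#' @export
print.displacement_profile <- function(x, ...) {
  cat(sprintf("<displacement_profile> %s: d_max = %g nm/ms, d_min = %g, L* = %g nm (anchor %g)\n",
              x$family, x$d_max, x$d_min, x$l_target, x$l_anchor))
  invisible(x)
}

# integer code shared with the compiled core
profile_family_code <- function(profile) {
  match(profile$family, c("linear_converging", "linear_floor",
                          "tent_nonconverging", "quadratic"))
}

#' Displacement rate at a given local density
#'
#' Evaluates a [displacement_profile()] at localized L value(s). Vectorised
#' over `l`.
#'
#' @param profile A `displacement_profile`.
#' @param l Localized L value(s) in nm, non-negative.
#' @return Displacement rate(s) in nm/ms.
#' @export
displacement_rate <- function(profile, l) {
  stopifnot(inherits(profile, "displacement_profile"), is.numeric(l), all(l >= 0))
  den <- profile$l_target - profile$l_anchor
  s <- pmin(1, pmax(0, (profile$l_target - l) / den))
  switch(profile$family,
         linear_converging = profile$d_max * s,
         linear_floor = pmax(profile$d_min, profile$d_max * s),
         tent_nonconverging = profile$d_max *
           pmin(1, abs(profile$l_target - l) / den),
         quadratic = profile$d_max * s^2)
}

#' Regular grid of reflective actin barriers
#'
#' The cortical actin meshwork is represented as a static square grid of
#' reflective line barriers (vertical lines at x = m * spacing and horizontal
#' lines at y = m * spacing). Barriers obstruct motion only; they are
#' transparent to density counting, since they sit beneath the membrane and
#' do not alter in-plane distances.
#'
#' @param spacing Grid pitch in nm (e.g. 250, 500, 1000). Must divide the box
#'   dimensions; this is checked when the mesh enters a [sim_config()].
#' @return An object of class `actin_mesh`.
#' @export
actin_mesh <- function(spacing) {
  stopifnot(is.numeric(spacing), length(spacing) == 1L, is.finite(spacing),
            spacing > 0)
  structure(list(spacing = as.numeric(spacing)), class = "actin_mesh")
}

#' @export
print.actin_mesh <- function(x, ...) {
  cat(sprintf("<actin_mesh> reflective grid, %g nm pitch\n", x$spacing))
  invisible(x)
}

#' Propose Brownian steps
#'
#' Draws one displacement per agent from the current R random-number stream.
#' In `"fixed"` mode the step length is exactly `rate * dt` in a direction
#' uniform on \eqn{[0, 2\pi)} (one uniform deviate per agent, in row order).
#' In `"gaussian"` mode each coordinate increment is a zero-mean normal with
#' per-axis standard deviation `rate * dt / sqrt(2)` (two normal deviates per
#' agent, x then y), so the RMS step length equals `rate * dt` and the two
#' modes are comparable at equal rate. Deviates are drawn for every agent,
#' including immobile ones, so the stream does not depend on the rates.
#'
#' @param p Positions: length-2 vector or n x 2 matrix, nm.
#' @param rate Displacement rate(s) in nm/ms, length 1 or n, non-negative.
#' @param dt Frame interval in ms.
#' @param mode `"fixed"` or `"gaussian"`.
#' @return Proposed (unwrapped) positions, same shape as `p`.
#' @export
propose_step <- function(p, rate, dt, mode = c("fixed", "gaussian")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(rate), all(rate >= 0), is.numeric(dt), length(dt) == 1L,
            dt > 0)
  pm <- as_xy(p)
  n <- nrow(pm)
  stopifnot(length(rate) %in% c(1L, n))
  len <- rep_len(rate, n) * dt
  if (mode == "fixed") {
    theta <- 2 * pi * stats::runif(n)
    step <- cbind(len * cos(theta), len * sin(theta))
  } else {
    z <- stats::rnorm(2L * n)
    sd <- len / sqrt(2)
    step <- cbind(z[seq(1L, 2L * n, by = 2L)] * sd,
                  z[seq(2L, 2L * n, by = 2L)] * sd)
  }
  out <- pm + step
  if (!is.matrix(p)) return(drop(out))
  out
}

#' Reflect proposed moves off the actin mesh
#'
#' Applies specular reflection about every mesh line crossed by the segment
#' from `old` to `proposed`, in crossing order, until no crossing remains.
#' For an axis-aligned grid this reduces to folding each coordinate back into
#' the mesh cell of the starting point, so a reflected agent never changes
#' mesh cell. Requires the step to be shorter than the mesh pitch (true for
#' all supported parameter sets), otherwise the traversal would be ambiguous.
#'
#' @param old Starting positions (inside the box, not on a mesh line):
#'   length-2 vector or n x 2 matrix, nm.
#' @param proposed Proposed (unwrapped) positions, same shape.
#' @param mesh An [actin_mesh()].
#' @return Reflected positions, same shape as `old`.
#' @examples
#' m <- actin_mesh(500)
#' reflect_off_mesh(c(490, 100), c(510, 100), m) # c(490, 100)
#' @export
reflect_off_mesh <- function(old, proposed, mesh) {
  stopifnot(inherits(mesh, "actin_mesh"))
  om <- as_xy(old); pm <- as_xy(proposed)
  stopifnot(nrow(om) == nrow(pm))
  step <- sqrt(rowSums((pm - om)^2))
  if (any(step >= mesh$spacing))
    stop("step length must be smaller than the mesh spacing")
  s <- mesh$spacing
  for (j in 1:2) {
    lo <- floor(om[, j] / s) * s
    hi <- lo + s
    v <- pm[, j]
    repeat {
      over <- v > hi
      v[over] <- 2 * hi[over] - v[over]
      under <- v < lo
      v[under] <- 2 * lo[under] - v[under]
      if (!any(v > hi | v < lo)) break
    }
    pm[, j] <- v
  }
  if (!is.matrix(old)) return(drop(pm))
  pm
}
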