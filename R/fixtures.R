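#' Generate a completely spatially random pattern
#'
#' Uniform i.i.d. points on the box — the CSR null used for calibration and
#' as ground truth for the analysis stages. Deterministic per seed.
#'
#' @param n Number of points.
#' @param box An [roi_box()].
#' @param seed Optional integer seed; when `NULL` the current RNG stream is
#'   used.
#' @return A [point_pattern()].
#' @export
generate_csr <- function(n, box = roi_box(3000, 3000), seed = NULL) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 0)
  if (!is.null(seed)) set.seed(seed)
  point_pattern(stats::runif(n) * box$width, stats::runif(n) * box$height, box)
}

#' Generate Gaussian blob clusters with known ground truth
#'
#' Each blob is an isotropic Gaussian of standard deviation `sigma` around
#' its centre, wrapped (not truncated) onto the torus; background points are
#' uniform. Returns the pattern together with the true generating labels so
#' cluster callers can be scored against ground truth.
#'
#' @param centres Blob centres: b x 2 matrix (nm).
#' @param sizes Points per blob, length b (recycled from length 1).
#' @param sigma Blob standard deviation(s) in nm, length 1 or b.
#' @param n_background Uniform background points (label 0).
#' @param box An [roi_box()].
#' @param seed Optional integer seed.
#' @return List with `pattern` (a [point_pattern()]) and `labels` (integer:
#'   0 background, 1..b blob membership).
#' @export
generate_blobs <- function(centres, sizes, sigma, n_background = 0,
                           box = roi_box(3000, 3000), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  centres <- as_xy(centres)
  b <- nrow(centres)
  sizes <- rep_len(as.integer(sizes), b)
  sigma <- rep_len(as.numeric(sigma), b)
  stopifnot(all(sizes >= 0), all(sigma > 0), n_background >= 0)
  xs <- ys <- numeric(0)
  labels <- integer(0)
  for (i in seq_len(b)) {
    xs <- c(xs, centres[i, 1] + stats::rnorm(sizes[i], sd = sigma[i]))
    ys <- c(ys, centres[i, 2] + stats::rnorm(sizes[i], sd = sigma[i]))
    labels <- c(labels, rep.int(i, sizes[i]))
  }
  if (n_background > 0) {
    xs <- c(xs, stats::runif(n_background) * box$width)
    ys <- c(ys, stats::runif(n_background) * box$height)
    labels <- c(labels, rep.int(0L, n_background))
  }
  if (length(xs)) {
    w <- wrap_torus(cbind(xs, ys), box)
    xs <- w[, 1]; ys <- w[, 2]
  }
  list(pattern = point_pattern(xs, ys, box), labels = labels)
}

#' Generate synthetic mean-L curves
#'
#' Deterministic base curves plus optional seeded Gaussian noise, used as
#' oracle inputs for the regime classifier:
#' * `"flat"` — constant at `base` (a CSR-like series);
#' * `"saturating"` — `base + amplitude * (1 - exp(-t / tau))`, a converged
#'   series with closed-form convergence time;
#' * `"ramp"` — `base + slope * t`, a still-converging series.
#'
#' @param times Frame times in s.
#' @param family Curve family.
#' @param base Baseline L in nm (default 100, the CSR level at R = 100).
#' @param amplitude Saturating rise in nm (default 80).
#' @param tau Saturation time constant in s (default 30).
#' @param slope Ramp slope in nm/s (default 0.3).
#' @param noise_sd Gaussian noise standard deviation in nm (default 0).
#' @param seed Optional integer seed for the noise.
#' @return Numeric L series, same length as `times`.
#' @export
generate_l_curve <- function(times, family = c("flat", "saturating", "ramp"),
                             base = 100, amplitude = 80, tau = 30,
                             slope = 0.3, noise_sd = 0, seed = NULL) {
  family <- match.arg(family)
  stopifnot(is.numeric(times), length(times) >= 1, noise_sd >= 0)
  if (!is.null(seed)) set.seed(seed)
  curve <- switch(family,
                  flat = rep(base, length(times)),
                  saturating = base + amplitude * (1 - exp(-times / tau)),
                  ramp = base + slope * times)
  if (noise_sd > 0) curve <- curve + stats::rnorm(length(times), sd = noise_sd)
  curve
}
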