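# Independent reference implementations used as oracles. These deliberately
# avoid the package's geometry/density code paths: distances are minimised
# explicitly over the nine periodic images.

oracle_image_disp <- function(p, q, w, h) {
  best <- NULL
  best_d <- Inf
  for (ix in -1:1) for (iy in -1:1) {
    d <- c(q[1] + ix * w - p[1], q[2] + iy * h - p[2])
    dd <- sum(d^2)
    if (dd < best_d) { best_d <- dd; best <- d }
  }
  best
}

oracle_image_dist <- function(p, q, w, h) {
  sqrt(sum(oracle_image_disp(p, q, w, h)^2))
}

# all-pairs neighbour counts over explicit image minimisation
oracle_counts <- function(x, y, w, h, r) {
  n <- length(x)
  k <- integer(n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (oracle_image_dist(c(x[i], y[i]), c(x[j], y[j]), w, h) <= r)
        k[i] <- k[i] + 1L
    }
  }
  k
}

# hand-rolled synchronous frame update mirroring the documented RNG order:
# one uniform (fixed mode) or an x/y pair of normals (gaussian) per agent,
# in index order, drawn whether or not the agent moves
oracle_step_frame <- function(x, y, w, h, r, profile, dt, mode,
                              mesh_spacing = 0) {
  n <- length(x)
  k <- oracle_counts(x, y, w, h, r)
  l <- sqrt(w * h * k / (pi * (n - 1)))
  rate <- vapply(l, function(li) {
    den <- profile$l_target - profile$l_anchor
    s <- min(1, max(0, (profile$l_target - li) / den))
    switch(profile$family,
           linear_converging = profile$d_max * s,
           linear_floor = max(profile$d_min, profile$d_max * s),
           tent_nonconverging = profile$d_max *
             min(1, abs(profile$l_target - li) / den),
           quadratic = profile$d_max * s^2)
  }, numeric(1))
  for (i in seq_len(n)) {
    if (mode == "fixed") {
      u <- runif(1)
      len <- rate[i] * dt
      sx <- len * cos(2 * pi * u); sy <- len * sin(2 * pi * u)
    } else {
      z <- rnorm(2)
      sd <- rate[i] * dt / sqrt(2)
      sx <- z[1] * sd; sy <- z[2] * sd
    }
    if (rate[i] > 0) {
      px <- x[i] + sx; py <- y[i] + sy
      if (mesh_spacing > 0) {
        fold <- function(ov, nv) {
          lo <- floor(ov / mesh_spacing) * mesh_spacing
          hi <- lo + mesh_spacing
          while (nv > hi || nv < lo) {
            if (nv > hi) nv <- 2 * hi - nv
            if (nv < lo) nv <- 2 * lo - nv
          }
          nv
        }
        px <- fold(x[i], px); py <- fold(y[i], py)
      }
      x[i] <- px %% w; y[i] <- py %% h
    }
  }
  list(x = x, y = y)
}

# closed-form convergence time of the saturating curve
# base + amplitude * (1 - exp(-t / tau)): first time the curve enters the
# plateau band |L(t) - L(t_end)| <= tol * L(t_end)
oracle_saturating_tstar <- function(base, amplitude, tau, tol, t_end = 300) {
  l_end <- base + amplitude * (1 - exp(-t_end / tau))
  -tau * log(tol * l_end / amplitude + exp(-t_end / tau))
}

random_pattern <- function(n, w = 3000, h = w) {
  point_pattern(runif(n) * w, runif(n) * h, roi_box(w, h))
}
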