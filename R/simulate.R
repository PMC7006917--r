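#' Simulation configuration
#'
#' Bundles the full description of one experiment. Defaults reproduce the
#' Standard Condition geometry: 2000 agents in a 3 x 3 um^2 toroidal patch,
#' 10 ms frames for 5 simulated minutes (30,000 frames), density radius
#' R = 100 nm.
#'
#' @param profile A [displacement_profile()].
#' @param box An [roi_box()]; default 3000 x 3000 nm.
#' @param n_agents Number of agent-molecules (default 2000).
#' @param dt Frame interval in ms (default 10).
#' @param duration Simulated time in s (default 300); `duration * 1000 / dt`
#'   must be a whole number of frames.
#' @param r Density-counting radius in nm (default 100; variants 50, 200).
#'   Must be less than half the smaller box dimension.
#' @param step_mode `"fixed"` (step length exactly `rate * dt`) or
#'   `"gaussian"` (normal increments with matching RMS step).
#' @param mesh Optional [actin_mesh()]; its spacing must divide both box
#'   dimensions, and the largest possible step (`d_max * dt`) must be smaller
#'   than the spacing.
#' @param seed Integer seed; one RNG stream per run, split deterministically
#'   into an initialisation stream and a motion stream so changing the step
#'   mode never perturbs the initial pattern.
#' @param record_every Store every `record_every`-th frame as a thinned
#'   snapshot (default 100, i.e. 1 s cadence at dt = 10 ms); 0 disables
#'   snapshot storage (the final frame is always kept).
#' @param update `"synchronous"` (default: all rates from the pre-move
#'   snapshot, order-independent) or `"asynchronous"` (agents updated one at
#'   a time in random order against the evolving pattern; reference
#'   implementation in R, intended for small sensitivity checks only).
#' @return An object of class `sim_config`.
#' @seealso [standard_condition()] for the reference parameter set.
#' @export
sim_config <- function(profile,
                       box = roi_box(3000, 3000),
                       n_agents = 2000,
                       dt = 10,
                       duration = 300,
                       r = 100,
                       step_mode = c("fixed", "gaussian"),
                       mesh = NULL,
                       seed = 1L,
                       record_every = 100L,
                       update = c("synchronous", "asynchronous")) {
  step_mode <- match.arg(step_mode)
  update <- match.arg(update)
  stopifnot(inherits(profile, "displacement_profile"), inherits(box, "roi_box"),
            is.numeric(n_agents), length(n_agents) == 1L, n_agents >= 0,
            is.numeric(dt), length(dt) == 1L, dt > 0,
            is.numeric(duration), length(duration) == 1L, duration > 0,
            is.numeric(r), length(r) == 1L, r > 0,
            is.numeric(seed), length(seed) == 1L,
            is.numeric(record_every), length(record_every) == 1L,
            record_every >= 0)
  n_frames <- duration * 1000 / dt
  if (abs(n_frames - round(n_frames)) > 1e-9)
    stop("duration must be a whole number of frames (duration * 1000 / dt)")
  if (r >= min(box$width, box$height) / 2)
    stop("r must be smaller than half the box dimension")
  if (!is.null(mesh)) {
    stopifnot(inherits(mesh, "actin_mesh"))
    for (dim in c(box$width, box$height)) {
      m <- dim / mesh$spacing
      if (abs(m - round(m)) > 1e-9)
        stop("mesh spacing must divide the box dimensions")
    }
    if (profile$d_max * dt >= mesh$spacing)
      stop("maximum step (d_max * dt) must be smaller than the mesh spacing")
  }
  structure(list(profile = profile, box = box,
                 n_agents = as.integer(n_agents), dt = as.numeric(dt),
                 duration = as.numeric(duration), r = as.numeric(r),
                 step_mode = step_mode, mesh = mesh, seed = as.integer(seed),
                 record_every = as.integer(record_every), update = update,
                 n_frames = as.integer(round(n_frames))),
            class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf("<sim_config> %d agents, %g x %g nm, dt = %g ms, %g s (%d frames), R = %g nm\n",
              x$n_agents, x$box$width, x$box$height, x$dt, x$duration,
              x$n_frames, x$r))
  print(x$profile)
  if (!is.null(x$mesh)) print(x$mesh)
  invisible(x)
}

#' Standard Condition configuration
#'
#' Convenience constructor for the reference parameter set: linearly
#' converging profile with `d_max = 3.5` nm/ms and full immobility at the
#' target (`d_min = 0`), with the clustering target given as a neighbour
#' count ("encircled molecules") and converted to an L target through
#' [l_from_count()].
#'
#' @param target_count Target number of molecules encircled within the
#'   density radius (7 is the CSR level; typical sweeps span 7 to 69).
#' @param d_max Maximum displacement rate in nm/ms.
#' @param n_agents,box,r,... Passed to [sim_config()].
#' @return A [sim_config()].
#' @examples
#' cfg <- standard_condition(target_count = 45, duration = 10, seed = 7)
#' @export
standard_condition <- function(target_count = 45, d_max = 3.5,
                               n_agents = 2000, box = roi_box(3000, 3000),
                               r = 100, ...) {
  lt <- l_from_count(target_count, n_agents, box_area(box))
  sim_config(profile = displacement_profile("linear_converging", d_max = d_max,
                                            l_target = lt),
             box = box, n_agents = n_agents, r = r, ...)
}

# derived motion seed so initialisation and motion use distinct streams
motion_seed <- function(seed) {
  as.integer((as.double(seed) * 69069 + 12345) %% 2147483647)
}

#' Initialise a completely spatially random pattern
#'
#' Draws `n_agents` positions i.i.d. uniform on the box from the current RNG
#' stream — the CSR initial condition of every simulation.
#'
#' @param config A [sim_config()].
#' @return A [point_pattern()].
#' @export
initialise_pattern <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_agents
  point_pattern(stats::runif(n) * config$box$width,
                stats::runif(n) * config$box$height,
                config$box)
}

#' Advance a pattern by one frame (reference implementation)
#'
#' Pure-R single-frame update used as the readable reference for the
#' compiled core and for the asynchronous update mode. The synchronous rule
#' is: (1) compute all localized L values from the current pattern, (2) map
#' them to displacement rates through the profile, (3) propose all steps
#' from the same pre-move snapshot (consuming RNG deviates for every agent
#' in index order), (4) apply mesh reflection, then the toroidal wrap.
#' In asynchronous mode agents are visited in a random order and each sees
#' the partially updated pattern (quadratic cost; small patterns only).
#'
#' @param pattern A [point_pattern()].
#' @param config A [sim_config()]; `config$n_agents` is ignored in favour of
#'   the pattern's size.
#' @return The updated [point_pattern()].
#' @export
step_frame <- function(pattern, config) {
  stopifnot(inherits(pattern, "point_pattern"), inherits(config, "sim_config"))
  n <- n_points(pattern)
  if (n < 2L) return(pattern)
  box <- pattern$box
  if (config$update == "asynchronous") return(step_frame_async(pattern, config))
  l <- local_l(pattern, config$r)
  rate <- displacement_rate(config$profile, l)
  old <- cbind(pattern$x, pattern$y)
  prop <- propose_step(old, rate, config$dt, mode = config$step_mode)
  still <- rate == 0
  prop[still, ] <- old[still, ]
  if (!is.null(config$mesh)) prop <- reflect_off_mesh(old, prop, config$mesh)
  prop <- wrap_torus(prop, box)
  point_pattern(prop[, 1], prop[, 2], box)
}

step_frame_async <- function(pattern, config) {
  n <- n_points(pattern)
  box <- pattern$box
  area <- box_area(box)
  x <- pattern$x; y <- pattern$y
  ord <- sample.int(n)
  for (i in ord) {
    d <- toroidal_distance(c(x[i], y[i]), cbind(x, y), box)
    k <- sum(d <= config$r) - 1L
    rate <- displacement_rate(config$profile, l_from_count(k, n, area))
    p <- propose_step(c(x[i], y[i]), rate, config$dt, mode = config$step_mode)
    if (rate > 0) {
      if (!is.null(config$mesh)) p <- reflect_off_mesh(c(x[i], y[i]), p, config$mesh)
      p <- wrap_torus(p, box)
      x[i] <- p[1]; y[i] <- p[2]
    }
  }
  point_pattern(x, y, box)
}

#' Run one simulation
#'
#' Seeds the RNG from `config$seed`, draws the CSR initial pattern, then
#' iterates the density -> rate -> step -> boundary update for
#' `config$n_frames` frames, recording the mean localized L of every frame
#' (from the pre-move density pass) plus thinned position snapshots.
#' Deterministic: identical `(config, seed)` gives bit-identical output.
#'
#' @param config A [sim_config()].
#' @param count_mode Neighbour-count maintenance in the compiled core:
#'   `"auto"` switches between a full recount and an exact incremental
#'   update depending on how many agents are mobile; `"full"` and
#'   `"incremental"` force one path (used to validate their equivalence).
#' @return An object of class `sim_trajectory`: list with `l_series` (nm,
#'   length `n_frames + 1`), `times` (s), `final_frame` (a
#'   [point_pattern()]), `frames` (thinned snapshots), `frame_times`, and the
#'   `config` echo.
#' @export
run_simulation <- function(config, count_mode = c("auto", "full", "incremental")) {
  stopifnot(inherits(config, "sim_config"))
  count_mode <- match.arg(count_mode)
  if (config$n_agents < 2L) stop("need at least 2 agents to simulate")
  set.seed(config$seed)
  p0 <- initialise_pattern(config)
  set.seed(motion_seed(config$seed))
  if (config$update == "asynchronous")
    return(run_simulation_async(p0, config))
  pr <- config$profile
  res <- C_run_sim(p0$x, p0$y, config$box$width, config$box$height, config$r,
                   config$dt, config$n_frames,
                   profile_family_code(pr), pr$d_max, pr$d_min, pr$l_target,
                   pr$l_anchor,
                   match(config$step_mode, c("fixed", "gaussian")) - 1L,
                   if (is.null(config$mesh)) 0 else config$mesh$spacing,
                   config$record_every,
                   match(count_mode, c("auto", "full", "incremental")) - 1L)
  frames <- lapply(res$snapshots, function(m)
    point_pattern(m[, 1], m[, 2], config$box))
  structure(list(l_series = as.numeric(res$l_series),
                 times = seq(0, config$n_frames) * config$dt / 1000,
                 final_frame = point_pattern(res$x, res$y, config$box),
                 frames = frames,
                 frame_times = as.numeric(res$snap_frames) * config$dt / 1000,
                 config = config),
            class = "sim_trajectory")
}

run_simulation_async <- function(p0, config) {
  nf <- config$n_frames
  l_series <- numeric(nf + 1)
  frames <- list()
  frame_times <- numeric(0)
  p <- p0
  for (f in seq_len(nf)) {
    l_series[f] <- mean_l(p, config$r)
    if (config$record_every > 0 && (f - 1L) %% config$record_every == 0L) {
      frames[[length(frames) + 1L]] <- p
      frame_times <- c(frame_times, (f - 1L) * config$dt / 1000)
    }
    p <- step_frame(p, config)
  }
  l_series[nf + 1] <- mean_l(p, config$r)
  structure(list(l_series = l_series,
                 times = seq(0, nf) * config$dt / 1000,
                 final_frame = p, frames = frames, frame_times = frame_times,
                 config = config),
            class = "sim_trajectory")
}

#' @export
print.sim_trajectory <- function(x, ...) {
  cat(sprintf("<sim_trajectory> %d frames, <L> %0.1f -> %0.1f nm (seed %d)\n",
              length(x$l_series) - 1L, x$l_series[1],
              x$l_series[length(x$l_series)], x$config$seed))
  invisible(x)
}

#' @export
plot.sim_trajectory <- function(x, ...) {
  graphics::plot(x$times, x$l_series, type = "l", xlab = "time (s)",
                 ylab = expression("<" * L^100 * "> (nm)"), ...)
  graphics::abline(h = x$config$profile$l_target, lty = 2, col = "red")
  invisible(x)
}

#' Run a seeded ensemble of replicate simulations
#'
#' Repeats [run_simulation()] over a list of seeds and averages the
#' mean-L series frame-wise. Per-replicate final frames are retained for
#' cluster analysis; thinned snapshots are dropped unless `keep_frames`.
#'
#' @param config A [sim_config()]; `config$seed` seeds replicate 1 when
#'   `seeds` is not given.
#' @param n_reps Number of replicates (the reference studies use 30).
#' @param seeds Optional integer vector of length `n_reps`.
#' @param keep_frames Keep thinned snapshots of every replicate (memory-heavy).
#' @return An object of class `sim_ensemble`: `times`, `mean_l`, `sd_l`,
#'   `runs` (list of `sim_trajectory`), `seeds`, `config`.
#' @export
run_ensemble <- function(config, n_reps = 30, seeds = NULL, keep_frames = FALSE) {
  stopifnot(inherits(config, "sim_config"), n_reps >= 1)
  if (is.null(seeds)) seeds <- config$seed + seq_len(n_reps) - 1L
  if (length(seeds) != n_reps)
    stop("seed list length must equal the number of replicates")
  runs <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    if (!keep_frames) cfg$record_every <- 0L
    run_simulation(cfg)
  })
  lmat <- vapply(runs, function(r) r$l_series,
                 numeric(length(runs[[1]]$l_series)))
  lmat <- matrix(lmat, ncol = n_reps)
  mu <- rowMeans(lmat)
  sd_l <- if (n_reps > 1)
    sqrt(rowSums((lmat - mu)^2) / (n_reps - 1))
  else rep(NA_real_, length(mu))
  structure(list(times = runs[[1]]$times, mean_l = mu, sd_l = sd_l,
                 runs = runs, seeds = as.integer(seeds), config = config),
            class = "sim_ensemble")
}

#' @export
print.sim_ensemble <- function(x, ...) {
  cat(sprintf("<sim_ensemble> %d replicates, <L> %0.1f -> %0.1f nm\n",
              length(x$runs), x$mean_l[1], x$mean_l[length(x$mean_l)]))
  invisible(x)
}

#' @rdname run_ensemble
#' @param ensemble A `sim_ensemble`.
#' @return `final_frames()`: list of per-replicate final [point_pattern()]s.
#' @export
final_frames <- function(ensemble) {
  stopifnot(inherits(ensemble, "sim_ensemble"))
  lapply(ensemble$runs, `[[`, "final_frame")
}
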