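#' Convergence time of a mean-L series
#'
#' The time at which the ensemble-mean localized L series settles onto a
#' horizontal asymptote distinct from the CSR level: the earliest time t*
#' such that every later value stays within `plateau_tol` (relative) of the
#' end value of the series, provided that end value exceeds
#' `csr_level + csr_margin`. (On ensemble-mean series the end value is
#' already an average over replicates, so no extra tail smoothing is
#' applied.)
#'
#' @param l_series Mean localized L per frame, nm.
#' @param times Frame times in s, same length.
#' @param csr_level L value of the CSR null (the counting radius, 100 nm by
#'   default).
#' @param plateau_tol Relative half-width of the plateau band (default 0.02).
#' @param csr_margin Minimum elevation (nm) of the asymptote above the CSR
#'   level for convergence to be meaningful (default 5).
#' @param min_plateau Minimum duration (s) the series must hold the plateau
#'   band before the end of the run (default 60). Without this requirement
#'   any continuous series would trivially sit near its own end value over
#'   its final frames, and a still-rising ramp would be mistaken for an
#'   asymptote.
#' @return Convergence time in s, or `NA` if the series has no asymptote
#'   distinct from CSR (including the case where it is still drifting at the
#'   end of the run).
#' @export
convergence_time <- function(l_series, times, csr_level = 100,
                             plateau_tol = 0.02, csr_margin = 5,
                             min_plateau = 60) {
  stopifnot(length(l_series) == length(times), length(l_series) >= 1)
  n <- length(l_series)
  l_end <- l_series[n]
  if (!(l_end > csr_level + csr_margin)) return(NA_real_)
  outside <- which(abs(l_series - l_end) > plateau_tol * l_end)
  tstar <- if (!length(outside)) times[1] else {
    last <- max(outside)
    if (last >= n) return(NA_real_)
    times[last + 1L]
  }
  if (times[n] - tstar < min_plateau) return(NA_real_)
  tstar
}

#' Convergence error
#'
#' Signed relative overshoot of the final mean L with respect to the target:
#' `(final_mean_l - l_target) / l_target`.
#'
#' @param final_mean_l Final (end-of-run) ensemble-mean L, nm.
#' @param l_target Target L, nm (> 0).
#' @return Dimensionless fraction, sign preserved.
#' @export
convergence_error <- function(final_mean_l, l_target) {
  stopifnot(is.numeric(l_target), all(l_target > 0))
  (final_mean_l - l_target) / l_target
}

#' Classify the convergence regime of a mean-L series
#'
#' Three mutually exclusive regimes:
#' * `"converged"` — the series reached a horizontal asymptote above the
#'   CSR band within the run ([convergence_time()] is defined);
#' * `"csr"` — the series ends inside the CSR band
#'   (`csr_level + csr_margin`) with negligible end-window trend;
#' * `"converging"` — elevated and/or still rising without a plateau.
#'
#' @inheritParams convergence_time
#' @param trend_tol Maximum end-window slope (nm/s) for the CSR call
#'   (default 0.02).
#' @param trend_window Length of the end window used for the trend fit, s
#'   (default 60).
#' @inheritParams convergence_time
#' @return One of `"converged"`, `"converging"`, `"csr"`.
#' @export
classify_regime <- function(l_series, times, csr_level = 100,
                            plateau_tol = 0.02, csr_margin = 5,
                            trend_tol = 0.02, trend_window = 60,
                            min_plateau = 60) {
  ct <- convergence_time(l_series, times, csr_level, plateau_tol, csr_margin,
                         min_plateau)
  if (!is.na(ct)) return("converged")
  n <- length(l_series)
  l_end <- l_series[n]
  win <- times >= times[n] - trend_window
  slope <- if (sum(win) >= 2)
    stats::coef(stats::lm.fit(cbind(1, times[win]), l_series[win]))[2]
  else 0
  if (l_end <= csr_level + csr_margin && slope <= trend_tol) "csr" else "converging"
}

#' Detect the aggregation cut-off of a target sweep
#'
#' The digitization cut-off: the smallest tested target whose ensemble
#' remains CSR and such that every larger tested target is CSR too (guarding
#' against single-target noise). The trivially CSR target (a target at the
#' CSR density itself) can be excluded via `trivial`.
#'
#' @param targets Numeric targets, any order (counts or L values; the
#'   cut-off index is the same either way since the map between them is
#'   monotone).
#' @param regimes Character regimes from [classify_regime()], same length.
#' @param trivial Targets to ignore as trivially CSR (e.g. the CSR-level
#'   target 7); default none.
#' @return The cut-off target, or `NA` if every tested target aggregates.
#' @export
detect_cutoff <- function(targets, regimes, trivial = NULL) {
  stopifnot(length(targets) == length(regimes))
  keep <- !(targets %in% trivial)
  targets <- targets[keep]; regimes <- regimes[keep]
  if (!length(targets)) return(NA_real_)
  ord <- order(targets)
  targets <- targets[ord]; regimes <- regimes[ord]
  is_csr <- regimes == "csr"
  suffix_csr <- rev(cumprod(rev(is_csr)) > 0)
  cand <- which(is_csr & suffix_csr)
  if (!length(cand)) return(NA_real_)
  targets[min(cand)]
}

#' Sweep clustering targets and classify regimes
#'
#' Runs a seeded ensemble at each target neighbour count, classifies the
#' ensemble-mean L series, and tabulates convergence time, error and final
#' level. The regime parameters are evaluated against the configured
#' density radius (`csr_level = config$r`).
#'
#' @param target_counts Integer-valued targets in encircled molecules.
#' @param config Base [sim_config()]; its profile's `l_target` is replaced
#'   per target via [l_from_count()].
#' @param n_reps Replicates per target.
#' @param seeds Optional seed matrix/vector of length
#'   `n_reps * length(target_counts)` (column-per-target order); defaults to
#'   a deterministic grid derived from `config$seed`.
#' @param trivial Targets treated as trivially CSR for the cut-off (default:
#'   those at or below the CSR expectation for the configured geometry).
#' @param keep_final_frames Attach per-target lists of final frames (for
#'   cluster descriptors).
#' @param ... Further arguments passed to [classify_regime()].
#' @return An object of class `target_sweep`: list with `results` (data
#'   frame: `target_count`, `target_l`, `regime`, `convergence_time_s`,
#'   `error`, `final_mean_l`), `cutoff`, and optionally `final_frames`.
#' @export
sweep_targets <- function(target_counts, config, n_reps = 5, seeds = NULL,
                          trivial = NULL, keep_final_frames = FALSE, ...) {
  stopifnot(inherits(config, "sim_config"), length(target_counts) >= 1)
  nt <- length(target_counts)
  if (is.null(seeds))
    seeds <- config$seed + seq_len(n_reps * nt) - 1L
  if (length(seeds) != n_reps * nt)
    stop("need n_reps * length(target_counts) seeds")
  seeds <- matrix(as.integer(seeds), nrow = n_reps)
  area <- box_area(config$box)
  if (is.null(trivial)) {
    csr_count <- count_from_l(config$r, config$n_agents, area)
    trivial <- target_counts[target_counts <= ceiling(csr_count)]
  }
  frames <- vector("list", nt)
  rows <- vector("list", nt)
  for (ti in seq_len(nt)) {
    k <- target_counts[ti]
    cfg <- config
    cfg$profile$l_target <- l_from_count(k, config$n_agents, area)
    ens <- run_ensemble(cfg, n_reps = n_reps, seeds = seeds[, ti])
    final_l <- ens$mean_l[length(ens$mean_l)]
    regime <- classify_regime(ens$mean_l, ens$times, csr_level = config$r, ...)
    rows[[ti]] <- data.frame(
      target_count = k,
      target_l = cfg$profile$l_target,
      regime = regime,
      convergence_time_s = convergence_time(ens$mean_l, ens$times,
                                            csr_level = config$r),
      error = convergence_error(final_l, cfg$profile$l_target),
      final_mean_l = final_l)
    if (keep_final_frames) frames[[ti]] <- final_frames(ens)
  }
  results <- do.call(rbind, rows)
  out <- list(results = results,
              cutoff = detect_cutoff(results$target_count, results$regime,
                                     trivial = trivial),
              trivial = trivial,
              config = config, n_reps = n_reps)
  if (keep_final_frames) {
    names(frames) <- as.character(target_counts)
    out$final_frames <- frames
  }
  structure(out, class = "target_sweep")
}

#' @export
print.target_sweep <- function(x, ...) {
  cat(sprintf("<target_sweep> %d targets x %d replicates, cut-off: %s\n",
              nrow(x$results), x$n_reps,
              if (is.na(x$cutoff)) "none" else format(x$cutoff)))
  print(x$results, row.names = FALSE)
  invisible(x)
}
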