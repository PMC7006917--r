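#' Read and write localization tables
#'
#' All modules exchange point patterns as delimited text with header columns
#' `x_nm,y_nm[,frame,id]` — the common denominator of single-molecule
#' localization exports. `read_locations()` returns the raw table;
#' `as_point_pattern()` lifts it (or one frame of it) onto a toroidal box.
#'
#' @param path File path.
#' @return `read_locations()`: a data frame with at least `x_nm` and `y_nm`.
#' @export
read_locations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("x_nm", "y_nm") %in% names(df)))
    stop("localization table must have columns x_nm and y_nm")
  df
}

#' @rdname read_locations
#' @param df A data frame with `x_nm`, `y_nm` and optionally `frame`.
#' @param box An [roi_box()] the coordinates live on.
#' @param frame Optional frame number to select when `df` has a `frame`
#'   column.
#' @export
as_point_pattern <- function(df, box, frame = NULL) {
  if (!is.null(frame)) {
    if (is.null(df$frame)) stop("no frame column in table")
    df <- df[df$frame == frame, , drop = FALSE]
  }
  point_pattern(df$x_nm, df$y_nm, box)
}

#' @rdname read_locations
#' @param pattern A [point_pattern()].
#' @param id Optional per-molecule ids (e.g. cluster labels) written as an
#'   `id` column.
#' @export
write_locations <- function(pattern, path, frame = NULL, id = NULL) {
  stopifnot(inherits(pattern, "point_pattern"))
  df <- data.frame(x_nm = pattern$x, y_nm = pattern$y)
  if (!is.null(frame)) df$frame <- frame
  if (!is.null(id)) {
    stopifnot(length(id) == n_points(pattern))
    df$id <- id
  }
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write the mean-L time series of a run
#'
#' CSV with columns `frame,time_s,mean_L_nm` (plus `sd_L_nm` for ensembles).
#'
#' @param run A `sim_trajectory` or `sim_ensemble`.
#' @param path Output file path.
#' @export
write_l_series <- function(run, path) {
  if (inherits(run, "sim_trajectory")) {
    df <- data.frame(frame = seq_along(run$l_series) - 1L,
                     time_s = run$times, mean_L_nm = run$l_series)
  } else if (inherits(run, "sim_ensemble")) {
    df <- data.frame(frame = seq_along(run$mean_l) - 1L,
                     time_s = run$times, mean_L_nm = run$mean_l,
                     sd_L_nm = run$sd_l)
  } else stop("run must be a sim_trajectory or sim_ensemble")
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a run manifest
#'
#' JSON echo of the configuration and seed(s) of a run or ensemble, so any
#' output table can be traced back to the exact experiment that produced it.
#'
#' @param run A `sim_trajectory` or `sim_ensemble`.
#' @param path Output file path.
#' @export
write_run_manifest <- function(run, path) {
  cfg <- run$config
  manifest <- list(
    n_agents = cfg$n_agents,
    box_nm = c(cfg$box$width, cfg$box$height),
    dt_ms = cfg$dt,
    duration_s = cfg$duration,
    n_frames = cfg$n_frames,
    density_radius_nm = cfg$r,
    profile = unclass(cfg$profile),
    step_mode = cfg$step_mode,
    mesh_spacing_nm = if (is.null(cfg$mesh)) NULL else cfg$mesh$spacing,
    update = cfg$update,
    seeds = if (inherits(run, "sim_ensemble")) run$seeds else cfg$seed)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}
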