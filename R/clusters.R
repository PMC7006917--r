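#' Call clusters by density connectivity
#'
#' Deterministic density-based cluster caller (DBSCAN-style) under toroidal
#' distance: molecules with at least `min_neighbors` neighbours within
#' `linking_radius` are core; cores within `linking_radius` of one another
#' are linked into one component; non-core molecules within
#' `linking_radius` of a core join its cluster; components smaller than
#' `min_size` are relabelled noise. Defaults (50 nm, 5, 5) are tuned for
#' nanocluster-scale point patterns of ~2000 molecules in a 3 x 3 um^2 ROI.
#'
#' @param pattern A [point_pattern()].
#' @param linking_radius Connectivity radius in nm (< half the box dimension).
#' @param min_neighbors Core-point threshold (neighbours, excluding self).
#' @param min_size Minimum cluster size; smaller components become noise.
#' @return Integer labels, one per molecule: 0 = noise, 1..K = clusters
#'   (consecutive ids).
#' @export
call_clusters <- function(pattern, linking_radius = 50, min_neighbors = 5,
                          min_size = 5) {
  stopifnot(inherits(pattern, "point_pattern"),
            is.numeric(linking_radius), linking_radius > 0,
            min_neighbors >= 1, min_size >= 1)
  box <- pattern$box
  if (linking_radius >= min(box$width, box$height) / 2)
    stop("linking_radius must be smaller than half the box dimension")
  n <- n_points(pattern)
  if (n < min_size) return(integer(n))
  raw <- as.integer(C_dbscan_torus(pattern$x, pattern$y,
                                   box$width, box$height,
                                   linking_radius, as.integer(min_neighbors)))
  if (max(raw) == 0L) return(raw)
  sizes <- tabulate(raw)
  keep <- which(sizes >= min_size)
  remap <- integer(length(sizes))
  remap[keep] <- seq_along(keep)
  out <- integer(n)
  pos <- raw > 0L
  out[pos] <- remap[raw[pos]]
  out
}

# wrap-aware centroid: circular mean of each axis treated as an angle
toroidal_centroid <- function(pattern) {
  box <- pattern$box
  cm <- function(v, len) {
    a <- 2 * pi * v / len
    (atan2(mean(sin(a)), mean(cos(a))) / (2 * pi)) %% 1 * len
  }
  c(cm(pattern$x, box$width), cm(pattern$y, box$height))
}

#' Cluster radius statistic
#'
#' Radius of a cluster given the member positions: `sqrt(2)` times the RMS
#' toroidal distance of the members to their wrap-aware centroid. This is
#' the radius of the uniform disc with the same RMS spread, so members
#' uniform on a disc of radius r give ~r, and an isotropic Gaussian blob of
#' standard deviation sigma gives ~2 sigma.
#'
#' @param pattern A [point_pattern()] holding the members of one cluster
#'   (at least 2 points).
#' @return Radius in nm.
#' @export
cluster_radius <- function(pattern) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (n_points(pattern) < 2L)
    stop("cluster radius is undefined for fewer than 2 members")
  ctr <- toroidal_centroid(pattern)
  d <- toroidal_distance(ctr, cbind(pattern$x, pattern$y), pattern$box)
  sqrt(2 * mean(d^2))
}

#' Cluster descriptor report
#'
#' Computes the four per-ROI descriptors from a labelled pattern: number of
#' clusters, percentage of molecules in clusters, mean molecules per cluster
#' and mean cluster radius, plus a per-cluster table (size, centroid,
#' radius). Means are reported as `NA` when no cluster was found.
#'
#' @param pattern A [point_pattern()].
#' @param labels Integer labels from [call_clusters()] (0 = noise).
#' @return An object of class `cluster_report`: list with `n_clusters`,
#'   `pct_clustered`, `mean_molecules_per_cluster`, `mean_cluster_radius`,
#'   `clusters` (data frame) and the `labels` echo.
#' @export
descriptor_report <- function(pattern, labels) {
  stopifnot(inherits(pattern, "point_pattern"),
            length(labels) == n_points(pattern))
  n <- n_points(pattern)
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids)) {
    rows <- lapply(ids, function(id) {
      sel <- labels == id
      sub <- point_pattern(pattern$x[sel], pattern$y[sel], pattern$box)
      ctr <- toroidal_centroid(sub)
      data.frame(cluster = id, size = sum(sel),
                 centroid_x = ctr[1], centroid_y = ctr[2],
                 radius = cluster_radius(sub))
    })
    tab <- do.call(rbind, rows)
  } else {
    tab <- data.frame(cluster = integer(0), size = integer(0),
                      centroid_x = numeric(0), centroid_y = numeric(0),
                      radius = numeric(0))
  }
  structure(list(n_clusters = length(ids),
                 pct_clustered = if (n) 100 * sum(labels > 0L) / n else 0,
                 mean_molecules_per_cluster =
                   if (length(ids)) mean(tab$size) else NA_real_,
                 mean_cluster_radius =
                   if (length(ids)) mean(tab$radius) else NA_real_,
                 clusters = tab, labels = labels),
            class = "cluster_report")
}

#' @export
print.cluster_report <- function(x, ...) {
  cat(sprintf("<cluster_report> %d clusters, %0.1f%% clustered, %0.1f molecules/cluster, radius %0.1f nm\n",
              x$n_clusters, x$pct_clustered,
              x$mean_molecules_per_cluster, x$mean_cluster_radius))
  invisible(x)
}

#' @rdname descriptor_report
#' @inheritParams call_clusters
#' @return `analyse_clusters()`: the [descriptor_report()] of the pattern
#'   clustered with the given parameters.
#' @export
analyse_clusters <- function(pattern, linking_radius = 50, min_neighbors = 5,
                             min_size = 5) {
  descriptor_report(pattern,
                    call_clusters(pattern, linking_radius, min_neighbors,
                                  min_size))
}

#' Ensemble-averaged cluster descriptors
#'
#' Applies the cluster caller to a list of final-frame patterns (one per
#' replicate) and averages the per-ROI descriptors across replicates, the
#' way figure-level summaries are reported.
#'
#' @param patterns A list of [point_pattern()]s, or a `sim_ensemble` (its
#'   final frames are used).
#' @inheritParams call_clusters
#' @return List with `per_roi` (data frame, one row per replicate) and
#'   `mean` (named numeric vector of the four descriptors; per-ROI means are
#'   averaged over the replicates in which they are defined).
#' @export
ensemble_descriptors <- function(patterns, linking_radius = 50,
                                 min_neighbors = 5, min_size = 5) {
  if (inherits(patterns, "sim_ensemble")) patterns <- final_frames(patterns)
  stopifnot(is.list(patterns), length(patterns) >= 1)
  rows <- lapply(seq_along(patterns), function(i) {
    rep_report <- analyse_clusters(patterns[[i]], linking_radius,
                                   min_neighbors, min_size)
    data.frame(replicate = i,
               n_clusters = rep_report$n_clusters,
               pct_clustered = rep_report$pct_clustered,
               mean_molecules_per_cluster = rep_report$mean_molecules_per_cluster,
               mean_cluster_radius = rep_report$mean_cluster_radius)
  })
  per_roi <- do.call(rbind, rows)
  list(per_roi = per_roi,
       mean = c(n_clusters = mean(per_roi$n_clusters),
                pct_clustered = mean(per_roi$pct_clustered),
                mean_molecules_per_cluster =
                  mean(per_roi$mean_molecules_per_cluster, na.rm = TRUE),
                mean_cluster_radius =
                  mean(per_roi$mean_cluster_radius, na.rm = TRUE)))
}
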