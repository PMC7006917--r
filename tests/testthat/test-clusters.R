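two_blob_fixture <- function(seed = 17) {
  generate_blobs(rbind(c(750, 1500), c(2250, 1500)), sizes = 100, sigma = 30,
                 n_background = 100, box = roi_box(3000), seed = seed)
}

test_that("sparse regular patterns yield no clusters", {
  b <- roi_box(3000)
  # 7x7 grid with 150 nm pitch: no molecule has any neighbour within 50 nm
  g <- expand.grid(x = seq(100, 1000, by = 150), y = seq(100, 1000, by = 150))
  p <- point_pattern(g$x, g$y, b)
  lab <- call_clusters(p, linking_radius = 50, min_neighbors = 5, min_size = 5)
  expect_true(all(lab == 0L))
  rep <- descriptor_report(p, lab)
  expect_equal(rep$n_clusters, 0)
  expect_equal(rep$pct_clustered, 0)
  expect_true(is.na(rep$mean_molecules_per_cluster))
  # degenerate: fewer molecules than min_size
  expect_equal(call_clusters(point_pattern(1:3, 1:3, b), 50, 5, 5), rep(0L, 3))
})

test_that("two Gaussian blobs plus background are recovered as two clusters", {
  fx <- two_blob_fixture()
  lab <- call_clusters(fx$pattern, 50, 5, 5)
  expect_equal(max(lab), 2L)
  # at least 95% of each blob's molecules end up in one called cluster
  for (blob in 1:2) {
    called <- lab[fx$labels == blob]
    main <- sort(table(called[called > 0]), decreasing = TRUE)[1]
    expect_gte(as.integer(main), 95)
  }
  rep <- descriptor_report(fx$pattern, lab)
  expect_equal(rep$n_clusters, 2)
  expect_equal(rep$pct_clustered, 66.7, tolerance = 0.05)
  expect_equal(rep$mean_molecules_per_cluster, 100, tolerance = 0.05)
})

test_that("cluster radius statistic matches closed forms", {
  b <- roi_box(3000)
  # coincident members: zero radius
  p0 <- point_pattern(rep(500, 5), rep(500, 5), b)
  expect_equal(cluster_radius(p0), 0)
  # 4 points at (+-a, 0), (0, +-a) around a centre: radius = sqrt(2)*a
  a <- 40
  p4 <- point_pattern(1000 + c(a, -a, 0, 0), 1000 + c(0, 0, a, -a), b)
  expect_equal(cluster_radius(p4), sqrt(2) * a)
  # uniform disc of radius 100: statistic converges to 100
  set.seed(19)
  th <- runif(2e4) * 2 * pi; rr <- 100 * sqrt(runif(2e4))
  pd <- point_pattern(1500 + rr * cos(th), 1500 + rr * sin(th), b)
  expect_equal(cluster_radius(pd), 100, tolerance = 0.02)
  # isotropic Gaussian blob of sd sigma: radius ~ 2*sigma
  blob <- generate_blobs(rbind(c(1500, 1500)), sizes = 2e4, sigma = 30,
                         box = b, seed = 20)$pattern
  expect_equal(cluster_radius(blob), 60, tolerance = 0.03)
  expect_error(cluster_radius(point_pattern(1, 1, b)), "fewer than 2")
})

test_that("seam-straddling clusters are measured through the wrap", {
  b <- roi_box(3000)
  # blob centred on the corner seam
  blob <- generate_blobs(rbind(c(0, 0)), sizes = 4000, sigma = 25, box = b,
                         seed = 23)$pattern
  expect_equal(cluster_radius(blob), 50, tolerance = 0.05)
  lab <- call_clusters(blob, 50, 5, 5)
  expect_equal(max(lab), 1L) # one cluster despite being split across corners
})

test_that("labels form a partition invariant to ordering and rigid translation", {
  fx <- two_blob_fixture(seed = 29)
  p <- fx$pattern
  lab <- call_clusters(p, 50, 5, 5)
  expect_true(all(lab %in% 0:max(lab)))
  expect_equal(length(lab), n_points(p))
  # permutation invariance up to label renaming
  set.seed(30)
  perm <- sample(n_points(p))
  p2 <- point_pattern(p$x[perm], p$y[perm], p$box)
  lab2 <- call_clusters(p2, 50, 5, 5)
  expect_equal(max(lab2), max(lab))
  # co-membership must agree for a sample of pairs
  idx <- sample(n_points(p), 60)
  same1 <- outer(lab[perm][idx], lab[perm][idx], "==") &
    lab[perm][idx] > 0
  same2 <- outer(lab2[idx], lab2[idx], "==") & lab2[idx] > 0
  expect_identical(same1, same2)
  # rigid toroidal translation
  sh <- wrap_torus(cbind(p$x + 1234.5, p$y + 987.6), p$box)
  p3 <- point_pattern(sh[, 1], sh[, 2], p$box)
  rep1 <- descriptor_report(p, lab)
  rep3 <- analyse_clusters(p3)
  expect_equal(rep3$n_clusters, rep1$n_clusters)
  expect_equal(rep3$pct_clustered, rep1$pct_clustered)
})

test_that("min_size filtering relabels small components as noise with consecutive ids", {
  b <- roi_box(3000)
  big <- generate_blobs(rbind(c(500, 500), c(2500, 2500)), sizes = c(50, 8),
                        sigma = 15, box = b, seed = 31)
  lab_all <- call_clusters(big$pattern, 50, 3, min_size = 5)
  expect_equal(max(lab_all), 2L)
  lab_strict <- call_clusters(big$pattern, 50, 3, min_size = 20)
  expect_equal(max(lab_strict), 1L)
  expect_equal(sort(unique(lab_strict)), c(0L, 1L))
})

test_that("ensemble descriptors average per-ROI values across replicates", {
  pats <- list(two_blob_fixture(41)$pattern, two_blob_fixture(43)$pattern)
  d <- ensemble_descriptors(pats)
  expect_equal(nrow(d$per_roi), 2)
  expect_equal(d$mean[["n_clusters"]], mean(d$per_roi$n_clusters))
  expect_equal(d$mean[["n_clusters"]], 2)
})
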