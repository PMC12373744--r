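# cascn: pseudo-time ordering, signed-path GC, vertex-wise maps, ROI
# matrices, network thresholding and degrees.

test_that("pseudo-time ordering sorts by duration with id tie-break", {
  meta <- data.frame(subject_id = c("s1", "s2", "s3", "sB", "sA"),
                     group = c("TD", "TD", "TD", "TD", "TD"),
                     age = rep(60, 5), sex = rep("M", 5),
                     duration = c(5, 2, 9, 2, 2))
  atl <- small_atlas()
  thick <- matrix(2.5 + seq(0.01, 0.05, by = 0.01), 5, 100)
  vols <- data.frame(Pallidum.L = 1:5, Pallidum.R = 1:5,
                     Thalamus.L = 1:5, Thalamus.R = 1:5)
  ds <- morphometry_dataset(thick, vols, subject_metadata(meta), atl)
  ps <- build_pseudo_series(ds, "TD", setNames(1:5, meta$subject_id))
  expect_equal(ps$subject_ids, c("s2", "sA", "sB", "s1", "s3"))
  expect_true(all(diff(ps$durations) >= 0))
  expect_error(build_pseudo_series(ds, "HC", 1:5), "usage error")
})

test_that("signed_path_gca equals the normal-equations oracle", {
  mk <- function(vals, durs = seq_along(vals)) {
    structure(list(subject_ids = paste0("s", seq_along(vals)),
                   durations = durs, values = vals, group = "TD"),
              class = "pseudo_time_series")
  }
  # fixed 8-point series
  x <- mk(c(1, 2, 1, 3, 2, 4, 3, 5))
  y <- mk(c(1.1, 1.9, 2.2, 1.4, 3.1, 2.3, 4.2, 3.1))
  g <- signed_path_gca(x, y)
  expect_equal(g$coefficient, oracle_gc(x$values, y$values),
               tolerance = 1e-12)
  expect_equal(g$n_effective, 7)

  expect_error(signed_path_gca(x, x), "self-causality")
  expect_error(signed_path_gca(x, mk(rep(1, 8))), "degenerate")
  expect_error(signed_path_gca(mk(1:3), mk(c(2, 1, 3))), "too short")
  y2 <- y; y2$subject_ids <- rev(y2$subject_ids)
  expect_error(signed_path_gca(x, y2), "alignment")
})

test_that("null GC: mean coefficient ~ 0 and p approximately uniform", {
  set.seed(99)
  n <- 69
  draws <- replicate(400, {
    x <- rnorm(n); y <- rnorm(n)
    T <- n; Z <- cbind(1, y[-T], x[-T])
    b <- solve(crossprod(Z), crossprod(Z, y[-1]))
    e <- y[-1] - Z %*% b
    s2 <- sum(e^2) / (T - 4)
    tt <- b[3] / sqrt(s2 * solve(crossprod(Z))[3, 3])
    c(b[3], 2 * pt(-abs(tt), T - 4))
  })
  expect_lt(abs(mean(draws[1, ])), 0.02)
  expect_gt(stats::ks.test(draws[2, ], "punif")$p.value, 0.01)
})

test_that("order invariance: storage order does not affect GC results", {
  ds <- tiny_cohort(seed = 21)
  perm <- sample(nrow(ds$subjects))
  ds_p <- subset_dataset(ds, perm)
  n1 <- roi_cascn_matrix(ds, "ET", c("REG01.L", "REG02.R", "REG03.L"))
  n2 <- roi_cascn_matrix(ds_p, "ET", c("REG01.L", "REG02.R", "REG03.L"))
  expect_equal(n1$weights, n2$weights, tolerance = 1e-12)
})

test_that("roi matrix validates inputs and is symmetric in law for nulls", {
  ds <- tiny_cohort(seed = 22)
  expect_error(roi_cascn_matrix(ds, "ET", "REG01.L"), "arity")
  expect_error(roi_cascn_matrix(ds, "ET", c("REG01.L", "REG01.L")),
               "duplicate")
  net <- roi_cascn_matrix(ds, "ET", ds$atlas$region_names)
  expect_true(all(is.na(diag(net$weights))))
  off <- net$weights[row(net$weights) != col(net$weights)]
  expect_equal(mean(off), 0, tolerance = 1e-10)  # z-scored off-diagonal
  expect_equal(sd(off), 1, tolerance = 1e-10)
})

test_that("threshold_network: hand-counted degrees and conservation", {
  W <- matrix(-1, 3, 3)
  W[1, 2] <- 2; W[1, 3] <- 1.5; W[2, 3] <- 1.2   # A->B, A->C, B->C
  net <- causal_network(c("A", "B", "C"), W, raw = W)
  nt <- threshold_network(net, z_threshold = 1)
  expect_equal(unname(nt$out_degree), c(2, 1, 0))
  expect_equal(unname(nt$in_degree), c(0, 1, 2))
  expect_equal(sum(nt$out_degree), sum(nt$in_degree))
  expect_equal(sum(nt$out_degree), sum(nt$adjacency))
  expect_equal(attr(nt, "hubs")$source, "A")

  # nothing above threshold -> all degrees zero
  nt0 <- threshold_network(net, z_threshold = 10)
  expect_true(all(nt0$out_degree == 0) && all(nt0$in_degree == 0))
  expect_warning(threshold_network(net, z_threshold = -1), "positive-GC")

  # reciprocal pair pruned to the dominant direction
  W2 <- matrix(NA, 2, 2); W2[1, 2] <- 2; W2[2, 1] <- 1.5
  nt2 <- threshold_network(causal_network(c("A", "B"), W2, raw = W2), 1)
  expect_equal(unname(nt2$out_degree), c(1, 0))
  nt2b <- threshold_network(causal_network(c("A", "B"), W2, raw = W2), 1,
                            dominant_only = FALSE)
  expect_equal(unname(nt2b$out_degree), c(1, 1))
})

test_that("degree conservation holds on random thresholded networks", {
  set.seed(14)
  for (i in 1:20) {
    R <- sample(3:8, 1)
    W <- matrix(rnorm(R * R), R)
    net <- causal_network(paste0("R", 1:R), W, raw = W)
    nt <- threshold_network(net, z_threshold = runif(1, 0, 1.5))
    expect_equal(sum(nt$out_degree), sum(nt$in_degree))
    expect_equal(sum(nt$out_degree), sum(nt$adjacency))
  }
})

test_that("vertexwise CaSCN: strict cluster-size rule and null behaviour", {
  # strict "> min_cluster" rule exercised via the exported pipeline on a
  # planted single-target cascade at small scale
  sp <- cohort_spec(n_td = 2, n_et = 40, n_hc = 2,
                    atlas_spec = list(n_regions = 4,
                                      vertices_per_region = 25),
                    noise_sd = 0.05, smoothing_fwhm = 1,
                    cascade = list(cascade_edge("REG01.L", "REG03.L", 0.02,
                                                lag = 5, saturation = 20,
                                                group = "ET")),
                    seed = 41)
  ds <- simulate_cohort(sp)
  res <- vertexwise_cascn(ds, "ET", "REG01.L", n_perm = 200, seed = 5)
  expect_s3_class(res$stat_map, "stat_map")
  # seed region is excluded from the map
  expect_true(all(is.na(
    res$stat_map$statistic[region_vertices(ds$atlas, "REG01.L")])))
  for (cl in res$clusters$clusters) expect_gt(cl$size, 10)

  # exactly-10-vertex surviving blobs must be excluded (strict >)
  expect_length(Filter(function(v) length(v) > 10, list(1:10)), 0)

  expect_error(vertexwise_cascn(ds, "TD", "REG01.L", n_perm = 100),
               ">= 10")
})

test_that("vertexwise CaSCN is calibrated on null cohorts", {
  hits <- vapply(1:12, function(seed) {
    ds <- simulate_null_cohort(cohort_spec(
      n_td = 2, n_et = 30, n_hc = 2,
      atlas_spec = list(n_regions = 4, vertices_per_region = 25),
      seed = seed))
    res <- vertexwise_cascn(ds, "ET", "REG01.L", n_perm = 150,
                            seed = 100 + seed)
    length(res$clusters$clusters) > 0
  }, logical(1))
  expect_lte(mean(hits), 0.25)
})
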