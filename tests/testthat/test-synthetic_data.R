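# synthetic_data: atlas generation, cohort simulation, planted effects.

test_that("make_atlas builds connected equal regions deterministically", {
  atl <- make_atlas(4, 25, seed = 1)
  expect_length(atl$vertex_ids, 100)
  expect_length(atl$region_names, 4)
  expect_equal(unname(table(atl$region_of_vertex)), rep(25L, 4),
               ignore_attr = TRUE)
  atl2 <- make_atlas(4, 25, seed = 1)
  expect_identical(atl[c("vertex_ids", "coords", "region_of_vertex",
                         "region_names", "edges")],
                   atl2[c("vertex_ids", "coords", "region_of_vertex",
                          "region_names", "edges")])
  expect_silent(validate_atlas(atl))
  expect_error(make_atlas(1, 25), "n_regions")
  expect_error(make_atlas(4, 3), "vertices_per_region")
})

test_that("atlas adjacency has no self-edges and regions are connected", {
  for (cfg in list(c(5, 9), c(6, 16), c(3, 7))) {
    atl <- make_atlas(cfg[1], cfg[2])
    expect_false(any(atl$edges[, 1] == atl$edges[, 2]))
    expect_silent(validate_atlas(atl))
  }
})

test_that("simulate_cohort is deterministic and respects invariants", {
  ds1 <- tiny_cohort(seed = 5)
  ds2 <- tiny_cohort(seed = 5)
  expect_identical(ds1$thickness, ds2$thickness)
  expect_identical(ds1$volumes, ds2$volumes)
  expect_identical(as.data.frame(ds1$subjects), as.data.frame(ds2$subjects))
  expect_true(all(ds1$thickness > 0))
  expect_false(anyNA(ds1$thickness))
  pat <- ds1$subjects$group != "HC"
  expect_true(all(!is.na(ds1$subjects$duration[pat])))
  expect_true(all(is.na(ds1$subjects$duration[!pat])))
  # HC clinical scores are explicit NA, not sentinels
  expect_true(all(is.na(ds1$subjects$MoCA[!pat])))
})

test_that("cascade naming and spec validation errors", {
  expect_error(cohort_spec(nonsense = 1), "unknown cohort_spec field")
  expect_error(cohort_spec(n_td = 1), "counts")
  sp <- tiny_spec(cascade = list(cascade_edge("NOPE.L", "REG01.L", 0.01)))
  expect_error(simulate_cohort(sp), "unknown region.*NOPE.L")
  expect_error(cascade_edge("a", "b", 1, lag = -1), "lag")
  expect_error(cascade_edge("a", "b", 1, saturation = 0), "saturation")
})

test_that("planted effect is linear in effect_rate below saturation", {
  mean_dev <- function(rate) {
    sp <- tiny_spec(seed = 3, cascade = list(
      cascade_edge("REG01.L", "REG03.L", rate, lag = 0, saturation = 100,
                   group = "TD")))
    ds <- simulate_cohort(sp)
    sp0 <- sp; sp0$cascade <- list()
    ds0 <- simulate_cohort(sp0)
    idx <- ds$subjects$group == "TD"
    vs <- region_vertices(ds$atlas, "REG01.L")
    mean(ds$thickness[idx, vs] - ds0$thickness[idx, vs])
  }
  d1 <- mean_dev(0.01)
  d2 <- mean_dev(0.02)
  expect_equal(d2, 2 * d1, tolerance = 1e-10)
})

test_that("noise field smoothness is recovered within 20%", {
  atl <- make_atlas(6, 100)
  for (fwhm in c(3, 5)) {
    f <- simulate_smooth_fields(atl, 60, fwhm = fwhm, seed = 42)
    est <- estimate_smoothness(f, atl)
    expect_gt(est$fwhm, 0.8 * fwhm)
    expect_lt(est$fwhm, 1.2 * fwhm)
  }
})

test_that("source's planted deviation leads the target's in pseudo-time", {
  # brute-force cross-correlation of the planted mean deviations: the
  # duration-ordered source deviation must correlate best with the target
  # deviation at a positive source-lead offset
  sp <- cohort_spec(n_td = 2, n_et = 60, n_hc = 2,
                    atlas_spec = list(n_regions = 4,
                                      vertices_per_region = 25),
                    noise_sd = 0.01,
                    duration_dist = list(TD = c(9.28, 7.16),
                                         ET = c(15, 9)),
                    cascade = list(cascade_edge("REG01.L", "REG03.L", 0.02,
                                                lag = 5, saturation = 10,
                                                group = "ET")),
                    seed = 11)
  ds <- simulate_cohort(sp)
  src <- build_pseudo_series(ds, "ET", "REG01.L")
  tgt <- build_pseudo_series(ds, "ET", "REG03.L")
  xc <- vapply(0:10, function(k) {
    n <- length(src$values)
    stats::cor(src$values[1:(n - k)], tgt$values[(1 + k):n])
  }, numeric(1))
  expect_gt(which.max(xc), 1)  # maximum at a positive source-lead offset
})

test_that("null cohort removes every planted effect", {
  sp <- tiny_spec(seed = 9, cascade = list(
    cascade_edge("REG01.L", "REG02.R", 0.05, group = "TD")))
  dsn <- simulate_null_cohort(sp)
  sp0 <- tiny_spec(seed = 9)
  sp0$cascade <- list()
  sp0$subcortical_effects <- lapply(sp0$subcortical_effects,
                                    function(x) { x[] <- 0; x })
  expect_identical(dsn$thickness, simulate_cohort(sp0)$thickness)
  expect_identical(dsn$volumes, simulate_cohort(sp0)$volumes)
})

test_that("pallidum shift is detected by the subcortical ANCOVA (power)", {
  # Monte-Carlo power run: TD-only pallidum shift ~ printed group difference
  hits <- vapply(1:100, function(seed) {
    sp <- cohort_spec(n_td = 69, n_et = 71, n_hc = 80,
                      atlas_spec = list(n_regions = 2,
                                        vertices_per_region = 4),
                      subcortical_effects = list(
                        Pallidum.L = c(TD = 270, ET = 0, HC = 0),
                        Pallidum.R = c(TD = 0, ET = 0, HC = 0),
                        Thalamus.L = c(TD = 0, ET = 0, HC = 0),
                        Thalamus.R = c(TD = 0, ET = 0, HC = 0)),
                      subcortical_sd = c(Pallidum.L = 450, Pallidum.R = 450,
                                         Thalamus.L = 450, Thalamus.R = 450),
                      seed = seed)
    ds <- simulate_cohort(sp)
    tab <- subcortical_ancova(ds)
    tab$p_fdr[tab$structure == "Pallidum.L"] < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
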