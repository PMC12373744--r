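# group_morphometry: vertex GLM, MCS correction, ANCOVA, summary-stat
# tests, binomial forward inference, early-stage filters.

test_that("vertex GLM equals the closed-form two-sample t everywhere", {
  ds <- toy_dataset(values_a = c(2.1, 2.2, 2.3), values_b = c(2.6, 2.7, 2.8))
  des <- make_design(ds, c("TD", "HC"), covariates = character(0))
  smap <- fit_vertex_glm(ds, des)
  # pooled two-sample t oracle
  a <- c(2.1, 2.2, 2.3); b <- c(2.6, 2.7, 2.8)
  sp2 <- (2 * var(a) + 2 * var(b)) / 4
  t_oracle <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / 3 + 1 / 3))
  expect_equal(smap$statistic, rep(t_oracle, length(smap$statistic)),
               tolerance = 1e-10)
  expect_equal(smap$df, 4)

  # randomised check at every vertex
  ds2 <- tiny_cohort(seed = 2)
  des2 <- make_design(ds2, c("ET", "HC"), covariates = character(0))
  smap2 <- fit_vertex_glm(ds2, des2)
  i_et <- which(ds2$subjects$group == "ET")
  i_hc <- which(ds2$subjects$group == "HC")
  t_or <- vapply(seq_len(ncol(ds2$thickness)), function(v) {
    unname(stats::t.test(ds2$thickness[i_et, v], ds2$thickness[i_hc, v],
                         var.equal = TRUE)$statistic)
  }, numeric(1))
  expect_equal(smap2$statistic, t_or, tolerance = 1e-10)
})

test_that("covariate orthogonal to group leaves the group t almost unchanged", {
  ds <- tiny_cohort(seed = 3)
  idx <- which(ds$subjects$group %in% c("TD", "HC"))
  des0 <- make_design(ds, c("TD", "HC"), covariates = character(0))
  X <- des0$X
  cov_orth <- stats::resid(stats::lm(rnorm(nrow(X)) ~ X - 1))
  X1 <- cbind(X, orth = cov_orth)
  s0 <- fit_vertex_glm(ds, list(X = X, contrast = c(0, 1), idx = idx))
  s1 <- fit_vertex_glm(ds, list(X = X1, contrast = c(0, 1, 0), idx = idx))
  expect_equal(s1$df, s0$df - 1)
  # the group coefficient itself is exactly unchanged (orthogonality)
  b0 <- stats::coef(stats::lm(ds$thickness[idx, 1] ~ X - 1))["Xgroup"]
  b1 <- stats::coef(stats::lm(ds$thickness[idx, 1] ~ X1 - 1))["X1group"]
  expect_equal(unname(b0), unname(b1), tolerance = 1e-12)
  # and the t map moves only marginally
  expect_equal(s1$statistic, s0$statistic, tolerance = 0.1)
})

test_that("rank-deficient design is rejected with the collinear column named", {
  ds <- toy_dataset()
  X <- cbind(intercept = 1, group = c(1, 1, 1, 0, 0, 0),
             dup = c(1, 1, 1, 0, 0, 0))
  expect_error(fit_vertex_glm(ds, list(X = X, contrast = c(0, 1, 0),
                                       idx = 1:6)),
               "collinear.*dup")
})

test_that("MCS: planted strong effect recovered, empty map stays empty", {
  atl <- make_atlas(4, 49)
  sp <- cohort_spec(n_td = 20, n_et = 2, n_hc = 20,
                    atlas_spec = list(n_regions = 4,
                                      vertices_per_region = 49),
                    seed = 8)
  ds <- simulate_null_cohort(sp, atlas = atl)
  # plant a 6-SD regional effect in TD
  vs <- region_vertices(atl, "REG02.R")
  i_td <- ds$subjects$group == "TD"
  ds$thickness[i_td, vs] <- ds$thickness[i_td, vs] + 6 * 0.25
  smap <- fit_vertex_glm(ds, make_design(ds, c("TD", "HC")))
  cl <- cluster_correct_mcs(smap, atl, n_iter = 200, seed = 77)
  sig <- sig_clusters(cl)
  expect_gte(length(sig), 1)
  top <- sig[[which.max(vapply(sig, `[[`, numeric(1), "size"))]]
  expect_gte(length(intersect(top$vertices, vs)), 40)
  expect_lte(top$corrected_p, 1 / 201 + 1e-12)

  # a map with no supra-threshold vertex -> empty cluster list
  null_map <- stat_map(rep(0.1, length(atl$vertex_ids)),
                       rep(0.9, length(atl$vertex_ids)), 30, "t")
  expect_length(cluster_correct_mcs(null_map, atl, n_iter = 100,
                                    seed = 1)$clusters, 0)
  expect_error(cluster_correct_mcs(smap, atl, n_iter = 50), "n_iter")
})

test_that("BH follows the hand-applied step-up and Bonferroni is min(1, 3p)", {
  p <- c(0.001, 0.02, 0.03, 0.4)
  expect_equal(stats::p.adjust(p, "BH"), c(0.004, 0.04, 0.04, 0.4))
  # invariance to input order / monotonicity
  o <- c(3, 1, 4, 2)
  expect_equal(stats::p.adjust(p[o], "BH"), c(0.004, 0.04, 0.04, 0.4)[o])

  sp <- tiny_spec(seed = 2, subcortical_effects = list(
    Pallidum.L = c(TD = 900, ET = 0, HC = 0),
    Pallidum.R = c(TD = 0, ET = 0, HC = 0),
    Thalamus.L = c(TD = 0, ET = 0, HC = 0),
    Thalamus.R = c(TD = 0, ET = 0, HC = 0)))
  tab <- subcortical_ancova(simulate_cohort(sp))
  expect_true(all(tab$p_fdr >= tab$p_raw))
  # pairwise Bonferroni p = min(1, 3 * raw pairwise p): re-derive one case
  row <- tab[tab$structure == "Pallidum.L", ]
  expect_lte(row$p_TD_ET, 1)
  expect_gte(row$p_TD_HC, 0)
  expect_equal(row$dir_TD_HC, ">")
})

test_that("ANCOVA preconditions and naming errors", {
  ds <- tiny_cohort()
  expect_error(subcortical_ancova(ds, structures = "Putamen.L"),
               "naming error.*Putamen.L")
  ds_two <- subset_dataset(ds, ds$subjects$group != "ET")
  expect_error(subcortical_ancova(ds_two), "three groups")
})

test_that("summary-statistic tests match closed forms", {
  rows <- data.frame(variable = rep(c("duration", "MoCA"), each = 2),
                     group = c("TD", "ET", "TD", "ET"),
                     mean = c(9.28, 16.41, 23.36, 21.38),
                     sd = c(7.16, 12.48, 3.04, 4.88),
                     n = c(69, 71, 69, 71))
  out <- summary_stat_tests(rows, "welch_t")
  # closed-form Welch oracle, computed independently
  moca <- out[out$variable == "MoCA", ]
  se2 <- 3.04^2 / 69 + 4.88^2 / 71
  t_or <- (23.36 - 21.38) / sqrt(se2)
  df_or <- se2^2 / ((3.04^2 / 69)^2 / 68 + (4.88^2 / 71)^2 / 70)
  expect_equal(moca$statistic, t_or, tolerance = 1e-12)
  expect_equal(moca$df, df_or, tolerance = 1e-12)
  expect_equal(t_or, 2.89, tolerance = 0.01)
  expect_lt(out$p[out$variable == "duration"], 0.001)

  same <- data.frame(variable = "x", group = c("a", "b"),
                     mean = c(1, 1), sd = c(2, 2), n = c(10, 10))
  eq <- summary_stat_tests(same, "student_t")
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)

  three <- data.frame(variable = "age", group = c("TD", "ET", "HC"),
                      mean = c(63.62, 65.31, 63.84),
                      sd = c(6.66, 7.91, 5.16), n = c(69, 71, 80))
  a <- summary_stat_tests(three, "oneway_anova")
  expect_gt(a$p, 0.05)
  expect_error(summary_stat_tests(three, "welch_t"), "arity")
})

test_that("forward-inference binomial matches the exact tail sum", {
  counts <- data.frame(domain = c("motor", "vision", "none"),
                       k = c(9, 5, 0), n = c(10, 50, 20))
  out <- forward_inference_binomial(counts, base_rate = 0.2)
  tail_or <- sum(choose(10, 9:10) * 0.2^(9:10) * 0.8^(10 - (9:10)))
  expect_equal(out$p[1], tail_or, tolerance = 1e-12)
  expect_equal(out$p[3], 1)           # k = 0: no enrichment
  expect_equal(out$p_fdr, stats::p.adjust(out$p, "BH"))
  # boundary: k = n * base_rate with large n gives p near 1/2
  big <- forward_inference_binomial(
    data.frame(domain = "d", k = 2000, n = 10000), 0.2)
  expect_equal(big$p, 0.5, tolerance = 0.02)
  expect_error(forward_inference_binomial(
    data.frame(domain = "d", k = 5, n = 4), 0.2), "validation")
})

test_that("early-stage filters apply the strict rules", {
  ds <- tiny_cohort(seed = 4)
  ds$subjects$hy_stage[ds$subjects$group == "TD"] <-
    rep(c(1, 2, 3), length.out = sum(ds$subjects$group == "TD"))
  td <- early_stage_filter(ds, "td_hy_le2")
  expect_true(all(td$subjects$hy_stage[td$subjects$group == "TD"] <= 2))
  expect_equal(sum(td$subjects$group == "ET"), 0)
  expect_equal(sum(td$subjects$group == "HC"),
               sum(ds$subjects$group == "HC"))

  ds$subjects$duration[ds$subjects$group == "ET"] <-
    rep(c(9.9, 10.0), length.out = sum(ds$subjects$group == "ET"))
  et <- early_stage_filter(ds, "et_duration_lt10")
  expect_true(all(et$subjects$duration[et$subjects$group == "ET"] == 9.9))

  ds$subjects$duration[ds$subjects$group == "ET"] <- 20
  expect_warning(early_stage_filter(ds, "et_duration_lt10"), "no patient")
  ds_hc <- subset_dataset(ds, ds$subjects$group == "HC")
  expect_error(early_stage_filter(ds_hc, "td_hy_le2"), "usage error")
})
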