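# Seed-based structural covariance network (SCN) analysis: seed extraction,
# the seed x group interaction GLM, a Fisher-z correlation-difference
# cross-check, and Gaussian-random-field cluster correction.

#' Extract a seed series
#'
#' Per-subject mean thickness over a region's vertices.
#'
#' @param dataset a `morphometry_dataset`.
#' @param region region name in the atlas.
#' @return object of class `seed_series`: list with `values` (named by
#'   subject id) and `region`.
#' @export
extract_seed <- function(dataset, region) {
  vs <- region_vertices(dataset$atlas, region)
  vals <- rowMeans(dataset$thickness[, vs, drop = FALSE])
  structure(list(values = vals, region = region), class = "seed_series")
}

#' Seed x group interaction map (SCN group difference)
#'
#' At each vertex fits
#' `thickness = b0 + b1 seed + b2 group + b3 (seed x group) + covariates`
#' over the patient group and HC, and returns the t map for the interaction
#' `b3`.  With patients coded 1, a negative `b3` means the seed-target
#' covariance is weaker in patients than HC ("covariance decreased").  The
#' seed's own vertices are excluded from the target set (stat 0, p 1) to
#' avoid trivially perfect covariance.
#'
#' @param dataset a `morphometry_dataset`.
#' @param seed a [extract_seed()] result from the same dataset.
#' @param patient_group `"TD"` or `"ET"` (compared against HC).
#' @param covariates metadata columns to adjust for (default age + sex; use
#'   `character(0)` for none).
#' @return a [stat_map()] of kind `"t"` with residuals attached; attribute
#'   `excluded` lists the masked seed vertices.
#' @export
scn_interaction_map <- function(dataset, seed, patient_group,
                                covariates = c("age", "sex")) {
  stopifnot(inherits(seed, "seed_series"))
  meta <- dataset$subjects
  idx <- which(meta$group %in% c(patient_group, "HC"))
  if (!any(meta$group[idx] == patient_group) || !any(meta$group[idx] == "HC")) {
    stop_fmt("both %s and HC must be present", patient_group)
  }
  s <- seed$values[idx]
  grp <- as.numeric(meta$group[idx] == patient_group)
  for (g in unique(grp)) {
    if (stats::sd(s[grp == g]) == 0) {
      stop_fmt("degenerate regressor: seed is constant within a group")
    }
  }
  s <- s - mean(s)
  X <- cbind(intercept = 1, seed = s, group = grp, interaction = s * grp)
  for (cv in covariates) {
    col <- meta[[cv]][idx]
    if (cv == "sex") col <- as.numeric(col == "M")
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- cv
  }
  contrast <- as.numeric(colnames(X) == "interaction")
  excl <- region_vertices(dataset$atlas, seed$region)
  Y <- dataset$thickness[idx, , drop = FALSE]
  fit <- ols_tmap(X, Y, contrast)
  tstat <- fit$t; p <- fit$p
  tstat[excl] <- 0; p[excl] <- 1
  res <- fit$residuals
  out <- stat_map(tstat, p, fit$df, "t", residuals = res)
  attr(out, "excluded") <- excl
  out
}

#' Fisher-z correlation-difference SCN map (cross-check)
#'
#' The classic SCN group comparison: per vertex, the seed-target Pearson
#' correlation is computed within each group, Fisher-z transformed, and the
#' standardised difference `(z_patient - z_HC) / sqrt(1/(n_p-3) + 1/(n_h-3))`
#' returned.  Exposed as an assumption-different validation route for
#' [scn_interaction_map()] (no covariate adjustment).
#'
#' @inheritParams scn_interaction_map
#' @return a [stat_map()] of kind `"z"`.
#' @export
scn_correlation_diff <- function(dataset, seed, patient_group) {
  meta <- dataset$subjects
  ip <- which(meta$group == patient_group)
  ih <- which(meta$group == "HC")
  if (length(ip) < 4 || length(ih) < 4) stop_fmt("need n >= 4 per group")
  cor_vec <- function(i) {
    drop(stats::cor(seed$values[i], dataset$thickness[i, , drop = FALSE]))
  }
  rp <- pmin(pmax(cor_vec(ip), -0.999999), 0.999999)
  rh <- pmin(pmax(cor_vec(ih), -0.999999), 0.999999)
  z <- (atanh(rp) - atanh(rh)) /
    sqrt(1 / (length(ip) - 3) + 1 / (length(ih) - 3))
  excl <- region_vertices(dataset$atlas, seed$region)
  z[excl] <- 0
  p <- clamp_p(2 * stats::pnorm(-abs(z)))
  p[excl] <- 1
  stat_map(z, p, Inf, "z")
}

#' Gaussian random field (GRF) cluster correction
#'
#' Cluster-level inference from random field theory for 2-D fields.  With
#' cluster-forming threshold `u` (z scale) and estimated smoothness FWHM:
#' expected cluster count per sign
#' `E[m] = R (4 log 2) (2 pi)^{-3/2} u exp(-u^2/2)` with resels
#' `R = V / FWHM^2`; expected supra-threshold vertices
#' `E[N] = V Phi(-u)`; cluster extent is approximately exponential for
#' D = 2, `P(n >= k) = exp(-k E[m]/E[N])`; the familywise corrected p of a
#' size-k cluster is `1 - exp(-2 E[m] P(n >= k))` (both signs counted).
#'
#' @param stat_map a [stat_map()]; t statistics are converted to z scale
#'   through their p-values.
#' @param atlas a `surface_atlas`.
#' @param smoothness a [estimate_smoothness()] result (typically from the
#'   GLM residual maps); estimated from the statistic map when omitted.
#' @param cluster_forming_p two-sided vertex threshold (default 0.01);
#'   values >= 0.05 trigger a warning (the extent approximation degrades at
#'   lenient thresholds).
#' @param alpha cluster-wise level (default 0.05).
#' @return a `cluster_result`.
#' @export
grf_cluster_correct <- function(stat_map, atlas, smoothness = NULL,
                                cluster_forming_p = 0.01, alpha = 0.05) {
  if (cluster_forming_p >= 0.05) {
    warn_fmt("GRF extent approximation is poor at cluster_forming_p >= 0.05")
  }
  if (is.null(smoothness)) {
    maps <- stat_map$residuals %||% matrix(stat_map$statistic, nrow = 1)
    smoothness <- estimate_smoothness(maps, atlas)
  }
  if (smoothness$fwhm <= 0) stop_fmt("invalid smoothness")
  obs <- observed_clusters(stat_map, atlas, cluster_forming_p)
  if (!length(obs)) return(cluster_result(list(), alpha, "grf"))
  V <- length(atlas$vertex_ids)
  u <- stats::qnorm(1 - cluster_forming_p / 2)
  R <- V / smoothness$fwhm^2
  Em <- R * 4 * log(2) * (2 * pi)^(-1.5) * u * exp(-u^2 / 2)
  EN <- V * stats::pnorm(u, lower.tail = FALSE)
  clusters <- lapply(obs, function(cl) {
    p_ext <- exp(-cl$size * Em / EN)
    cp <- 1 - exp(-2 * Em * p_ext)
    cp <- min(max(cp, .Machine$double.xmin), 1)
    c(cl, list(corrected_p = cp, significant = cp < alpha))
  })
  cluster_result(clusters, alpha, "grf")
}
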