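# Vertex-wise general linear model and Monte-Carlo cluster correction.

#' Build a two-group design matrix with covariates
#'
#' Rows follow the dataset's subject order restricted to `groups`; columns
#' are intercept, a group indicator (1 for the first group listed), and the
#' requested covariates (`sex` is coded M = 1, F = 0).  The returned object
#' carries the contrast vector selecting the group column.
#'
#' @param dataset a `morphometry_dataset`.
#' @param groups length-2 character, e.g. `c("TD", "HC")`; the first is
#'   coded 1.
#' @param covariates character subset of metadata columns (default
#'   `c("age", "sex")`).
#' @return list with `X` (design matrix), `contrast`, and `idx` (subject
#'   rows used).
#' @export
make_design <- function(dataset, groups, covariates = c("age", "sex")) {
  meta <- dataset$subjects
  idx <- which(meta$group %in% groups)
  if (!length(idx)) stop_fmt("no subjects in groups %s",
                             paste(groups, collapse = "/"))
  X <- cbind(intercept = 1,
             group = as.numeric(meta$group[idx] == groups[1]))
  for (cv in covariates) {
    col <- meta[[cv]][idx]
    if (cv == "sex") col <- as.numeric(col == "M")
    X <- cbind(X, col)
    colnames(X)[ncol(X)] <- cv
  }
  contrast <- as.numeric(colnames(X) == "group")
  list(X = X, contrast = contrast, idx = idx)
}

# Core vectorised OLS over many outcome columns sharing one design.
# Returns t map, p map, df, and the residual matrix.
ols_tmap <- function(X, Y, contrast) {
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    dropped <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    stop_fmt("design error: rank-deficient design; collinear column(s): %s",
             paste(dropped, collapse = ", "))
  }
  XtXi <- chol2inv(chol(crossprod(X)))
  B <- XtXi %*% crossprod(X, Y)
  E <- Y - X %*% B
  df <- nrow(X) - ncol(X)
  s2 <- colSums(E^2) / df
  cv <- drop(t(contrast) %*% XtXi %*% contrast)
  cb <- drop(contrast %*% B)
  se <- sqrt(s2 * cv)
  tstat <- ifelse(se > 0, cb / se, 0)
  p <- clamp_p(2 * stats::pt(-abs(tstat), df))
  list(t = tstat, p = p, df = df, residuals = E, coef = cb)
}

#' Per-vertex statistic map
#'
#' @param statistic per-vertex statistic values.
#' @param p per-vertex two-sided p in (0, 1].
#' @param df residual degrees of freedom.
#' @param kind `"t"`, `"z"` or `"gc"`.
#' @param residuals optional residual matrix kept for smoothness estimation.
#' @return object of class `stat_map`.
#' @export
stat_map <- function(statistic, p, df, kind = c("t", "z", "gc"),
                     residuals = NULL) {
  kind <- match.arg(kind)
  if (length(statistic) != length(p)) stop_fmt("statistic/p length mismatch")
  if (any(p <= 0 | p > 1, na.rm = TRUE)) stop_fmt("p must lie in (0, 1]")
  structure(list(statistic = statistic, p = p, df = df, kind = kind,
                 residuals = residuals),
            class = "stat_map")
}

#' @export
print.stat_map <- function(x, ...) {
  cat(sprintf("stat_map (%s, df = %.1f): %d vertices, max |stat| = %.3f\n",
              x$kind, x$df, length(x$statistic),
              max(abs(x$statistic), na.rm = TRUE)))
  invisible(x)
}

#' Vertex-wise GLM t-map for a contrast
#'
#' Ordinary-least-squares fit of each thickness column on the design, with
#' the two-sided t statistic of the given contrast and
#' `df = n - rank(design)`.
#'
#' @param dataset a `morphometry_dataset`.
#' @param design a design from [make_design()], or a plain matrix whose
#'   rows align with all dataset subjects.
#' @param contrast numeric contrast vector (taken from the design when it
#'   carries one).
#' @return a [stat_map()] of kind `"t"` with residuals attached.
#' @export
fit_vertex_glm <- function(dataset, design, contrast = NULL) {
  if (is.list(design) && !is.null(design$X)) {
    X <- design$X
    contrast <- contrast %||% design$contrast
    Y <- dataset$thickness[design$idx, , drop = FALSE]
  } else {
    X <- design
    Y <- dataset$thickness
  }
  if (is.null(contrast)) stop_fmt("a contrast vector is required")
  if (length(contrast) != ncol(X)) {
    stop_fmt("contrast length %d != design columns %d",
             length(contrast), ncol(X))
  }
  if (nrow(X) != nrow(Y)) stop_fmt("design rows do not align with subjects")
  fit <- ols_tmap(X, Y, contrast)
  stat_map(fit$t, fit$p, fit$df, "t", residuals = fit$residuals)
}

#' Cluster result container
#' @param clusters list of per-cluster lists (`vertices`, `size`,
#'   `peak_vertex`, `peak_stat`, `sign`, `corrected_p`, `significant`).
#' @param alpha significance level used.
#' @param method correction method label.
#' @return object of class `cluster_result`.
#' @export
cluster_result <- function(clusters, alpha, method) {
  structure(list(clusters = clusters, alpha = alpha, method = method),
            class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  sig <- sum(vapply(x$clusters, `[[`, logical(1), "significant"))
  cat(sprintf("cluster_result (%s): %d cluster(s), %d significant at alpha = %g\n",
              x$method, length(x$clusters), sig, x$alpha))
  invisible(x)
}

#' @export
as.data.frame.cluster_result <- function(x, ...) {
  if (!length(x$clusters)) {
    return(data.frame(size = integer(0), peak_vertex = integer(0),
                      peak_stat = numeric(0), sign = integer(0),
                      corrected_p = numeric(0), significant = logical(0)))
  }
  do.call(rbind, lapply(x$clusters, function(cl) {
    data.frame(size = cl$size, peak_vertex = cl$peak_vertex,
               peak_stat = cl$peak_stat, sign = cl$sign,
               corrected_p = cl$corrected_p, significant = cl$significant)
  }))
}

# Supra-threshold clusters of an observed map, sign-split so each cluster
# is single-signed (an "increase" or a "decrease", never mixed).
observed_clusters <- function(stat_map, atlas, cluster_forming_p) {
  supra <- !is.na(stat_map$p) & stat_map$p < cluster_forming_p
  out <- list()
  for (sgn in c(1, -1)) {
    mask <- supra & sign(stat_map$statistic) == sgn
    for (vs in clusters_from_mask(atlas, mask)) {
      peak <- vs[which.max(abs(stat_map$statistic[vs]))]
      out[[length(out) + 1L]] <- list(
        vertices = vs, size = length(vs), peak_vertex = peak,
        peak_stat = stat_map$statistic[peak], sign = sgn)
    }
  }
  out
}

# Maximum supra-threshold cluster size of one null z-field.
max_cluster_size <- function(atlas, field, z_thresh) {
  mx <- 0L
  for (sgn in c(1, -1)) {
    cl <- clusters_from_mask(atlas, sgn * field > z_thresh)
    if (length(cl)) mx <- max(mx, max(lengths(cl)))
  }
  mx
}

#' Monte-Carlo simulation (MCS) cluster correction
#'
#' FreeSurfer-style cluster-wise correction: supra-threshold vertices
#' (two-sided `p < cluster_forming_p`, sign-split) are grouped into
#' connected components; the null distribution of the maximum cluster size
#' is built from `n_iter` synthesised Gaussian fields smoothed to the
#' smoothness estimated from the observed map; each observed cluster gets
#' `corrected_p = (1 + #\{null max size >= observed size\}) / (n_iter + 1)`
#' (the add-one convention avoids zero p-values).
#'
#' @param stat_map a [stat_map()].
#' @param atlas a `surface_atlas`.
#' @param cluster_forming_p vertex-level two-sided screening threshold
#'   (default 0.01).
#' @param alpha cluster-wise significance level (default 0.05).
#' @param n_iter Monte-Carlo iterations (>= 100; default 1000).
#' @param seed optional RNG seed.
#' @param smoothness optional [estimate_smoothness()] result; estimated
#'   from the map itself when omitted.
#' @return a `cluster_result`.
#' @export
cluster_correct_mcs <- function(stat_map, atlas, cluster_forming_p = 0.01,
                                alpha = 0.05, n_iter = 1000, seed = NULL,
                                smoothness = NULL) {
  if (n_iter < 100) {
    stop_fmt("configuration error: n_iter must be >= 100 (tail unstable)")
  }
  if (length(stat_map$statistic) != length(atlas$vertex_ids)) {
    stop_fmt("stat_map length != atlas vertex count")
  }
  obs <- observed_clusters(stat_map, atlas, cluster_forming_p)
  if (!length(obs)) return(cluster_result(list(), alpha, "mcs"))
  if (is.null(smoothness)) {
    smoothness <- estimate_smoothness(stat_map$statistic, atlas)
  }
  local_seed(seed)
  z_thresh <- stats::qnorm(1 - cluster_forming_p / 2)
  null_max <- integer(n_iter)
  for (b in seq_len(n_iter)) {
    field <- drop(simulate_smooth_fields(atlas, 1, smoothness$fwhm))
    null_max[b] <- max_cluster_size(atlas, field, z_thresh)
  }
  clusters <- lapply(obs, function(cl) {
    cp <- (1 + sum(null_max >= cl$size)) / (n_iter + 1)
    c(cl, list(corrected_p = cp, significant = cp < alpha))
  })
  cluster_result(clusters, alpha, "mcs")
}

#' Group-label permutation cluster correction
#'
#' Assumption-light alternative to [cluster_correct_mcs()]: the null
#' maximum cluster size is obtained by refitting the GLM after permuting
#' the rows of the group-contrast column block, rather than by synthesising
#' Gaussian fields.
#'
#' @param dataset a `morphometry_dataset`.
#' @param design a design from [make_design()].
#' @param atlas the dataset atlas.
#' @inheritParams cluster_correct_mcs
#' @return a `cluster_result`.
#' @export
cluster_correct_permutation <- function(dataset, design, atlas,
                                        cluster_forming_p = 0.01,
                                        alpha = 0.05, n_iter = 1000,
                                        seed = NULL) {
  if (n_iter < 100) {
    stop_fmt("configuration error: n_iter must be >= 100 (tail unstable)")
  }
  smap <- fit_vertex_glm(dataset, design)
  obs <- observed_clusters(smap, atlas, cluster_forming_p)
  if (!length(obs)) return(cluster_result(list(), alpha, "permutation"))
  local_seed(seed)
  Y <- dataset$thickness[design$idx, , drop = FALSE]
  gcol <- which(design$contrast != 0)
  null_max <- integer(n_iter)
  for (b in seq_len(n_iter)) {
    Xp <- design$X
    Xp[, gcol] <- Xp[sample(nrow(Xp)), gcol]
    fit <- ols_tmap(Xp, Y, design$contrast)
    supra <- fit$p < cluster_forming_p
    mx <- 0L
    for (sgn in c(1, -1)) {
      cl <- clusters_from_mask(atlas, supra & sign(fit$t) == sgn)
      if (length(cl)) mx <- max(mx, max(lengths(cl)))
    }
    null_max[b] <- mx
  }
  clusters <- lapply(obs, function(cl) {
    cp <- (1 + sum(null_max >= cl$size)) / (n_iter + 1)
    c(cl, list(corrected_p = cp, significant = cp < alpha))
  })
  cluster_result(clusters, alpha, "permutation")
}
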