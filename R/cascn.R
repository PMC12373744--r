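# Causal structural covariance network (CaSCN) analysis.
#
# A cross-sectional patient cohort is re-ordered by disease duration to
# form a pseudo-time series; bivariate signed-path Granger causality
# (first-order autoregression with a lagged exogenous term) then yields a
# signed coefficient for every source -> target pair.  Vertex-wise maps
# keep positive coefficients, standardise them to z, and are calibrated by
# permuting the duration ordering; ROI-to-ROI matrices are thresholded into
# a binary directed network whose in/out-degrees identify putative
# progression sources and sinks.

#' Build a pseudo-time series for one patient group
#'
#' Orders the subjects of `group` by ascending disease duration (ties
#' broken by ascending subject id, a stable deterministic rule) and carries
#' the supplied per-subject values along.
#'
#' @param dataset a `morphometry_dataset`.
#' @param group `"TD"` or `"ET"` (HC has no durations and is a usage
#'   error).
#' @param values per-subject values: either a numeric vector named by
#'   subject id (or aligned with the group's subjects in dataset order), or
#'   a region name to use that region's mean thickness.
#' @param detrend_covariates if `TRUE`, age and sex are regressed out of
#'   the values (within the group) before ordering.
#' @return object of class `pseudo_time_series`: `subject_ids`,
#'   `durations` (non-decreasing), `values`.
#' @export
build_pseudo_series <- function(dataset, group, values,
                                detrend_covariates = FALSE) {
  if (group == "HC") {
    stop_fmt("usage error: HC has no disease durations; pseudo-time needs TD or ET")
  }
  meta <- dataset$subjects
  idx <- which(meta$group == group)
  if (!length(idx)) stop_fmt("no %s subjects in dataset", group)
  if (is.character(values) && length(values) == 1) {
    values <- extract_seed(dataset, values)$values[idx]
  } else if (!is.null(names(values))) {
    values <- values[as.character(meta$subject_id[idx])]
    if (anyNA(values)) stop_fmt("values missing for some %s subjects", group)
  } else if (length(values) != length(idx)) {
    stop_fmt("values length %d != %s group size %d", length(values), group,
             length(idx))
  }
  values <- as.numeric(values)
  if (detrend_covariates) {
    X <- cbind(1, meta$age[idx], as.numeric(meta$sex[idx] == "M"))
    values <- drop(values - X %*% qr.solve(X, values))
  }
  ord <- order(meta$duration[idx], as.character(meta$subject_id[idx]))
  structure(list(subject_ids = as.character(meta$subject_id[idx])[ord],
                 durations = meta$duration[idx][ord],
                 values = values[ord], group = group),
            class = "pseudo_time_series")
}

# Vectorised first-order signed-path GC: for each column y of Y fit
#   y_t = a + b y_{t-1} + c x_{t-1},  t = 2..T
# by OLS via partitioned (demeaned) normal equations, returning the signed
# path coefficient c, its t statistic and two-sided p per column.
gc_map <- function(Y, x) {
  T <- length(x)
  yl <- Y[-T, , drop = FALSE]   # y_{t-1}
  yt <- Y[-1, , drop = FALSE]   # y_t
  xl <- x[-T]                   # x_{t-1}
  m <- T - 1                    # effective observations
  cyl <- sweep(yl, 2, colMeans(yl))
  cyt <- sweep(yt, 2, colMeans(yt))
  cxl <- xl - mean(xl)
  Saa <- colSums(cyl^2)
  Sbb <- sum(cxl^2)
  Sab <- colSums(cyl * cxl)
  Say <- colSums(cyl * cyt)
  Sby <- colSums(cxl * cyt)
  Syy <- colSums(cyt^2)
  det <- Saa * Sbb - Sab^2
  ok <- det > .Machine$double.eps * pmax(Saa * Sbb, 1)
  b1 <- ifelse(ok, (Sbb * Say - Sab * Sby) / det, NA)
  cc <- ifelse(ok, (Saa * Sby - Sab * Say) / det, NA)
  df <- m - 3
  s2 <- pmax(Syy - b1 * Say - cc * Sby, 0) / df
  se <- sqrt(s2 * Saa / det)
  tstat <- ifelse(ok & se > 0, cc / se, NA)
  p <- clamp_p(2 * stats::pt(-abs(tstat), df))
  list(coefficient = cc, t = tstat, p = p, n_effective = m, df = df)
}

#' Bivariate signed-path Granger causality
#'
#' Fits `y_t = a + b y_{t-1} + c x_{t-1}` by ordinary least squares over
#' the shared pseudo-time ordering and reports the signed path coefficient
#' `c` with its t-test p-value.  Self-causality (`x` identical to `y`) is
#' rejected.  Model order is fixed at 1: pseudo-time has no true sampling
#' interval and higher orders overfit series of this length.
#'
#' @param x,y `pseudo_time_series` objects with identical subject
#'   orderings (source `x`, target `y`).
#' @param order autoregressive order; only 1 is supported.
#' @return object of class `gc_result`: `coefficient`, `t`, `p`,
#'   `n_effective` (= series length - order), `z` (NA for a single pair;
#'   filled by map/matrix standardisation).
#' @export
signed_path_gca <- function(x, y, order = 1) {
  stopifnot(inherits(x, "pseudo_time_series"),
            inherits(y, "pseudo_time_series"))
  if (order != 1) stop_fmt("only model order 1 is supported")
  if (!identical(x$subject_ids, y$subject_ids)) {
    stop_fmt("alignment error: x and y must share the same subject ordering")
  }
  T <- length(x$values)
  if (T <= order + 2) stop_fmt("series too short: length %d <= order + 2", T)
  if (stats::sd(x$values) == 0 || stats::sd(y$values) == 0) {
    stop_fmt("degenerate regressor: constant pseudo-time series")
  }
  if (identical(x$values, y$values)) {
    stop_fmt("usage error: self-causality (x identical to y) is undefined")
  }
  res <- gc_map(matrix(y$values, ncol = 1), x$values)
  structure(list(coefficient = res$coefficient[1], t = res$t[1],
                 p = res$p[1], n_effective = res$n_effective, z = NA_real_),
            class = "gc_result")
}

#' @export
print.gc_result <- function(x, ...) {
  cat(sprintf("gc_result: c = %.4g, t = %.3f, p = %.4g, n_eff = %d\n",
              x$coefficient, x$t, x$p, x$n_effective))
  invisible(x)
}

#' Vertex-wise CaSCN from a seed region
#'
#' Computes the signed-path GC coefficient from the seed region's
#' pseudo-time series to every vertex's series.  Negative coefficients are
#' discarded; the surviving coefficients are standardised to z across the
#' retained vertices.  Significance is calibrated by permuting the duration
#' ordering `n_perm` times with max-statistic familywise control
#' (`corrected_p = (1 + #\{null max z >= z_v\}) / (n_perm + 1)`); vertices
#' with corrected p below `alpha` are clustered and clusters with strictly
#' more than `min_cluster` vertices retained.  The seed region's own
#' vertices are excluded.
#'
#' @param dataset a `morphometry_dataset`.
#' @param group `"TD"` or `"ET"` (needs >= 10 patients).
#' @param seed_region seed region name.
#' @param order AR order (1).
#' @param alpha corrected significance level (default 0.05).
#' @param min_cluster clusters must exceed this many vertices (strict >;
#'   default 10).
#' @param n_perm permutations of the duration ordering (default 1000).
#' @param seed optional RNG seed.
#' @param detrend_covariates regress age/sex out of every series first.
#' @return list with `stat_map` (kind `"gc"`; statistic = z over retained
#'   vertices, NA elsewhere), `clusters` (a `cluster_result`), and
#'   `coefficients` (raw signed path coefficients).
#' @export
vertexwise_cascn <- function(dataset, group, seed_region, order = 1,
                             alpha = 0.05, min_cluster = 10, n_perm = 1000,
                             seed = NULL, detrend_covariates = FALSE) {
  meta <- dataset$subjects
  idx <- which(meta$group == group)
  if (length(idx) < 10) stop_fmt("need >= 10 %s patients", group)
  if (order != 1) stop_fmt("only model order 1 is supported")
  svs <- region_vertices(dataset$atlas, seed_region)

  ord <- order(meta$duration[idx], as.character(meta$subject_id[idx]))
  rows <- idx[ord]
  Y <- dataset$thickness[rows, , drop = FALSE]
  if (detrend_covariates) {
    X <- cbind(1, meta$age[rows], as.numeric(meta$sex[rows] == "M"))
    Y <- Y - X %*% qr.solve(X, Y)
  }
  x <- rowMeans(Y[, svs, drop = FALSE])
  # scale-free series: coefficients comparable across vertices and with the
  # seed regardless of deviation amplitude
  x <- (x - mean(x)) / max(stats::sd(x), 1e-12)
  Y <- apply(Y, 2, function(v) (v - mean(v)) / max(stats::sd(v), 1e-12))

  zscore_pos <- function(cc) {
    cc[svs] <- NA
    pos <- !is.na(cc) & cc > 0
    z <- rep(NA_real_, length(cc))
    if (sum(pos) >= 2 && stats::sd(cc[pos]) > 0) {
      z[pos] <- (cc[pos] - mean(cc[pos])) / stats::sd(cc[pos])
    }
    z
  }

  res <- gc_map(Y, x)
  z_obs <- zscore_pos(res$coefficient)
  if (all(is.na(z_obs))) {
    warn_fmt("no positive GC coefficients; empty CaSCN result")
    p_corr <- rep(1, length(z_obs))
    sm <- stat_map(rep(NA_real_, length(z_obs)), p_corr, res$df, "gc")
    return(list(stat_map = sm, clusters = cluster_result(list(), alpha, "permutation"),
                coefficients = res$coefficient))
  }

  local_seed(seed)
  T <- nrow(Y)
  null_max <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    pm <- sample(T)
    rb <- gc_map(Y[pm, , drop = FALSE], x[pm])
    zb <- zscore_pos(rb$coefficient)
    null_max[b] <- if (all(is.na(zb))) -Inf else max(zb, na.rm = TRUE)
  }
  p_corr <- rep(1, length(z_obs))
  keep <- !is.na(z_obs)
  p_corr[keep] <- vapply(z_obs[keep], function(z) {
    (1 + sum(null_max >= z)) / (n_perm + 1)
  }, numeric(1))

  surviving <- keep & p_corr < alpha
  cls <- clusters_from_mask(dataset$atlas, surviving)
  cls <- Filter(function(vs) length(vs) > min_cluster, cls)  # strict >
  clusters <- lapply(cls, function(vs) {
    peak <- vs[which.max(z_obs[vs])]
    list(vertices = vs, size = length(vs), peak_vertex = peak,
         peak_stat = z_obs[peak], sign = 1L,
         corrected_p = min(p_corr[vs]), significant = TRUE)
  })
  sm <- stat_map(z_obs, clamp_p(p_corr), res$df, "gc")
  list(stat_map = sm,
       clusters = cluster_result(clusters, alpha, "permutation"),
       coefficients = res$coefficient)
}

#' Directed causal network container
#'
#' @param nodes ROI names.
#' @param weights directed weight matrix (rows = source, columns = target;
#'   diagonal NA).
#' @param raw optional unstandardised coefficient matrix.
#' @return object of class `causal_network` (adjacency and degrees empty
#'   until [threshold_network()]).
#' @export
causal_network <- function(nodes, weights, raw = NULL) {
  stopifnot(is.matrix(weights), nrow(weights) == length(nodes),
            ncol(weights) == length(nodes))
  dimnames(weights) <- list(nodes, nodes)
  diag(weights) <- NA
  structure(list(nodes = nodes, weights = weights, raw = raw,
                 adjacency = NULL, in_degree = NULL, out_degree = NULL),
            class = "causal_network")
}

#' @export
print.causal_network <- function(x, ...) {
  ne <- if (is.null(x$adjacency)) NA_integer_ else sum(x$adjacency)
  cat(sprintf("causal_network: %d nodes%s\n", length(x$nodes),
              if (is.na(ne)) " (unthresholded)"
              else sprintf(", %d directed edges", ne)))
  if (!is.null(x$out_degree)) {
    cat(sprintf("  highest out-degree: %s (%d); highest in-degree: %s (%d)\n",
                x$nodes[which.max(x$out_degree)], max(x$out_degree),
                x$nodes[which.max(x$in_degree)], max(x$in_degree)))
  }
  invisible(x)
}

#' ROI-to-ROI CaSCN matrix
#'
#' Signed-path GC coefficient from every ROI's pseudo-time series to every
#' other's, z-scored over the off-diagonal entries.  Each series is
#' standardised (mean 0, SD 1) before the autoregressive fits so that
#' coefficients are scale-free and the two directions of a pair are
#' comparable regardless of the regions' deviation amplitudes.
#'
#' @param dataset a `morphometry_dataset`.
#' @param group `"TD"` or `"ET"`.
#' @param rois at least 2 unique region names.
#' @param order AR order (1).
#' @param detrend_covariates regress age/sex out of the series first.
#' @return a `causal_network` with weights (z) and `raw` coefficients;
#'   adjacency left empty.
#' @export
roi_cascn_matrix <- function(dataset, group, rois, order = 1,
                             detrend_covariates = FALSE) {
  if (length(rois) < 2) stop_fmt("arity error: need >= 2 ROIs")
  if (anyDuplicated(rois)) {
    stop_fmt("naming error: duplicate ROI name(s): %s",
             paste(unique(rois[duplicated(rois)]), collapse = ", "))
  }
  series <- lapply(rois, function(r) {
    build_pseudo_series(dataset, group, r,
                        detrend_covariates = detrend_covariates)
  })
  R <- length(rois)
  S <- vapply(series, `[[`, numeric(length(series[[1]]$values)), "values")
  S <- apply(S, 2, function(v) (v - mean(v)) / max(stats::sd(v), 1e-12))
  W <- matrix(NA_real_, R, R)
  P <- matrix(NA_real_, R, R)
  for (i in seq_len(R)) {
    res <- gc_map(S[, -i, drop = FALSE], S[, i])
    W[i, -i] <- res$coefficient
    P[i, -i] <- res$p
  }
  off <- W[upper.tri(W) | lower.tri(W)]
  Wz <- (W - mean(off)) / stats::sd(off)
  net <- causal_network(rois, Wz, raw = W)
  dimnames(P) <- list(rois, rois)
  net$p <- P
  net
}

#' Threshold a causal network into a binary directed graph
#'
#' An edge i -> j survives when the underlying coefficient is positive
#' (only positive GC carries the progression interpretation), it exceeds
#' the mode's threshold, and -- by default -- it beats its reciprocal
#' (`weights[i, j] > weights[j, i]`, the "net Granger causality"
#' convention: on duration-ordered pseudo-time series the reverse of a
#' true influence is itself a fair shape predictor and routinely clears
#' any fixed threshold, so the directed reading lives in the
#' forward-minus-reverse contrast).  Mode `"z"` thresholds the z-scored
#' weight matrix at `z_threshold`; mode `"significance"` keeps edges whose
#' GC t-test p is below `p_threshold` (the reading closest to the
#' vertex-wise stage, which also gates on significance).  Binary in-/
#' out-degrees are the column/row sums with the diagonal excluded; the
#' node of maximal out-degree is the candidate progression source.
#'
#' @param network a `causal_network` with weights (and `p` for
#'   significance mode, as produced by [roi_cascn_matrix()]).
#' @param z_threshold threshold on the z-scored weights (default 1; values
#'   below 0 trigger a warning under the positive-only convention).
#' @param mode `"z"` (default) or `"significance"`.
#' @param p_threshold per-edge significance level for mode
#'   `"significance"` (default 0.05).
#' @param dominant_only prune each reciprocal pair to its stronger
#'   direction (default TRUE).
#' @return the network with `adjacency`, `in_degree`, `out_degree` filled
#'   and a `hubs` attribute naming the argmax nodes.
#' @export
threshold_network <- function(network, z_threshold = 1,
                              mode = c("z", "significance"),
                              p_threshold = 0.05,
                              dominant_only = TRUE) {
  mode <- match.arg(mode)
  stopifnot(inherits(network, "causal_network"))
  if (is.null(network$weights)) stop_fmt("network has no weights")
  if (z_threshold < 0) {
    warn_fmt("z_threshold < 0 conflicts with the positive-GC convention")
  }
  W <- network$weights
  pos <- if (!is.null(network$raw)) network$raw > 0 else W > 0
  if (mode == "z") {
    A <- (!is.na(W)) & (W >= z_threshold) & pos
  } else {
    if (is.null(network$p)) {
      stop_fmt("significance mode needs a network with per-edge p-values")
    }
    A <- (!is.na(W)) & (network$p < p_threshold) & pos
  }
  if (dominant_only) A <- A & (is.na(t(W)) | W > t(W))
  storage.mode(A) <- "integer"
  diag(A) <- 0L
  network$adjacency <- A
  network$out_degree <- rowSums(A)
  network$in_degree <- colSums(A)
  attr(network, "hubs") <- list(
    source = network$nodes[which.max(network$out_degree)],
    sink = network$nodes[which.max(network$in_degree)])
  network
}
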