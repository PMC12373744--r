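# Smooth Gaussian fields on the grid mesh, and smoothness (FWHM) estimation.
#
# White noise convolved with a separable Gaussian kernel of standard
# deviation sigma = FWHM / (2 sqrt(2 log 2)) has autocorrelation
# rho(d) = exp(-d^2 / (4 sigma^2)) between vertices at lattice distance d.
# The smoothness estimator inverts that relation from the variance of
# nearest-neighbour differences (the classic Forman/AFNI estimator adapted
# to graph adjacency).

FWHM_SIGMA <- 2 * sqrt(2 * log(2))  # = 2.3548...: FWHM of a Gaussian / sd

gaussian_kernel_1d <- function(fwhm) {
  sigma <- fwhm / FWHM_SIGMA
  if (sigma < 0.05) return(1)       # effectively unsmoothed
  r <- max(1L, ceiling(3 * sigma))
  k <- stats::dnorm(seq(-r, r), sd = sigma)
  k / sum(k)
}

# Band matrix applying the kernel to a padded axis of length n + 2*pad,
# returning n values (interior crop, so no edge renormalisation is needed).
kernel_matrix <- function(n, k) {
  r <- (length(k) - 1L) %/% 2L
  np <- n + 2L * r
  K <- matrix(0, n, np)
  for (i in seq_len(n)) K[i, i:(i + 2L * r)] <- k
  K
}

#' Simulate smooth Gaussian random fields on an atlas mesh
#'
#' Generates `n` independent zero-mean Gaussian fields over the atlas
#' vertices with pointwise standard deviation `sd` and spatial smoothness
#' `fwhm` (in vertex units).  White noise is generated on the padded
#' bounding grid, convolved with a separable Gaussian kernel, cropped, and
#' rescaled so the marginal variance is exactly `sd^2` (no edge effects).
#'
#' @param atlas a `surface_atlas`.
#' @param n number of independent fields.
#' @param fwhm smoothing kernel FWHM in vertex spacings; values below ~0.1
#'   give white noise.
#' @param sd marginal standard deviation of each field.
#' @param seed optional integer seed (caller's RNG state is preserved).
#' @return an `n` x `n_vertices` matrix.
#' @export
simulate_smooth_fields <- function(atlas, n, fwhm, sd = 1, seed = NULL) {
  local_seed(seed)
  nr <- max(atlas$coords$row); nc <- max(atlas$coords$col)
  k <- gaussian_kernel_1d(fwhm)
  r <- (length(k) - 1L) %/% 2L
  Kr <- kernel_matrix(nr, k)
  Kc <- kernel_matrix(nc, k)
  scale <- sd / sum(k^2)  # convolved white noise has sd = sum(k^2) per axis pair
  vidx <- cbind(atlas$coords$row, atlas$coords$col)
  out <- matrix(0, n, length(atlas$vertex_ids))
  nrp <- nr + 2L * r; ncp <- nc + 2L * r
  for (i in seq_len(n)) {
    noise <- matrix(stats::rnorm(nrp * ncp), nrp, ncp)
    f <- Kr %*% noise %*% t(Kc)
    out[i, ] <- f[vidx] * scale
  }
  out
}

#' Estimate field smoothness (FWHM) from maps on an atlas
#'
#' Uses the variance of nearest-neighbour differences over the atlas edges:
#' for a Gaussian-autocorrelation field, `var(x_i - x_j) / (2 var(x)) =
#' 1 - exp(-1 / (4 sigma^2))` for adjacent i, j, which is inverted for
#' sigma and converted to FWHM.  Estimates below one vertex spacing are
#' floored at 1 (the lattice resolution limit; white noise reports 1).
#'
#' @param maps numeric vector (one map) or matrix (maps in rows, typically
#'   GLM residual maps) over the atlas vertices.
#' @param atlas a `surface_atlas`.
#' @return object of class `smoothness_estimate`: list with `fwhm` (vertex
#'   units) and `resels` (vertex count / fwhm^2).
#' @export
estimate_smoothness <- function(maps, atlas) {
  if (is.vector(maps)) maps <- matrix(maps, nrow = 1)
  if (ncol(maps) != length(atlas$vertex_ids)) {
    stop_fmt("maps have %d columns but atlas has %d vertices",
             ncol(maps), length(atlas$vertex_ids))
  }
  e1 <- atlas$edges[, 1]; e2 <- atlas$edges[, 2]
  v_tot <- mean(apply(maps, 1, stats::var))
  if (!is.finite(v_tot) || v_tot <= 0) {
    stop_fmt("undefined smoothness: residual maps are constant")
  }
  d2 <- (maps[, e1, drop = FALSE] - maps[, e2, drop = FALSE])^2
  v_diff <- mean(d2)
  ratio <- v_diff / (2 * v_tot)
  fwhm <- if (ratio >= 1) {
    1
  } else {
    sigma2 <- -1 / (4 * log(1 - ratio))
    max(1, FWHM_SIGMA * sqrt(sigma2))
  }
  structure(list(fwhm = fwhm,
                 resels = length(atlas$vertex_ids) / fwhm^2),
            class = "smoothness_estimate")
}

#' @export
print.smoothness_estimate <- function(x, ...) {
  cat(sprintf("smoothness_estimate: FWHM = %.3f vertices, %.1f resels\n",
              x$fwhm, x$resels))
  invisible(x)
}
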