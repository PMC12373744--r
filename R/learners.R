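# Minimal in-package learners.
#
# No SVM or random-forest library ships in the target environment, so the
# five learners of the classification protocol are provided here: a compact
# CART-style random forest, and L2-regularised kernel logistic regression
# with the four classic SVM kernels (linear, polynomial, RBF, sigmoid).
# The kernel machines return calibrated probabilities directly, which is
# what the AUC evaluation consumes.

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with tie handling: the probability a
#' random positive scores above a random negative, counting ties as 1/2.
#'
#' @param scores numeric predicted scores/probabilities.
#' @param labels binary labels (logical, 0/1, or a factor whose second
#'   level is the positive class).
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(scores, labels) {
  y <- as_binary(labels)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary <- function(labels) {
  if (is.factor(labels)) as.numeric(labels == levels(labels)[2])
  else as.numeric(as.logical(labels) | labels == 1)
}

# ---- random forest -------------------------------------------------------

# One CART tree on a bootstrap sample; split search is vectorised over the
# sorted candidate thresholds of each tried feature (Gini impurity).
grow_tree <- function(x, y, mtry, min_node) {
  build <- function(idx) {
    n <- length(idx)
    p1 <- mean(y[idx])
    if (n < min_node || p1 == 0 || p1 == 1) {
      return(list(leaf = TRUE, prob = p1))
    }
    feats <- sample.int(ncol(x), mtry)
    best <- NULL; best_gain <- 0
    n1 <- sum(y[idx])
    gini_parent <- 2 * p1 * (1 - p1)
    for (f in feats) {
      v <- x[idx, f]
      o <- order(v)
      vs <- v[o]; ys <- y[idx][o]
      cuts <- which(diff(vs) > 0)
      if (!length(cuts)) next
      cl1 <- cumsum(ys)[cuts]; cln <- cuts
      cr1 <- n1 - cl1; crn <- n - cln
      gl <- 2 * (cl1 / cln) * (1 - cl1 / cln)
      gr <- 2 * (cr1 / crn) * (1 - cr1 / crn)
      gain <- gini_parent - (cln * gl + crn * gr) / n
      j <- which.max(gain)
      if (gain[j] > best_gain) {
        best_gain <- gain[j]
        best <- list(feature = f, cut = (vs[cuts[j]] + vs[cuts[j] + 1]) / 2)
      }
    }
    if (is.null(best)) return(list(leaf = TRUE, prob = p1))
    left <- idx[x[idx, best$feature] <= best$cut]
    right <- setdiff(idx, left)
    list(leaf = FALSE, feature = best$feature, cut = best$cut,
         left = build(left), right = build(right))
  }
  build(seq_along(y))
}

predict_tree <- function(node, xrow) {
  while (!node$leaf) {
    node <- if (xrow[node$feature] <= node$cut) node$left else node$right
  }
  node$prob
}

#' Fit a random forest classifier
#'
#' Bagged CART trees with Gini splits and per-node random feature
#' subsampling; predicted probability is the mean of leaf class
#' frequencies.  A compact in-package implementation (no forest library is
#' assumed present).
#'
#' @param x numeric feature matrix.
#' @param y binary labels.
#' @param n_trees number of trees (default 500).
#' @param mtry features tried per split (default `floor(sqrt(p))`).
#' @param min_node minimum node size to attempt a split (default 5).
#' @param seed optional RNG seed.
#' @return object of class `cascnet_rf`.
#' @export
rf_fit <- function(x, y, n_trees = 500, mtry = NULL, min_node = 5,
                   seed = NULL) {
  local_seed(seed)
  y <- as_binary(y)
  x <- as.matrix(x)
  mtry <- mtry %||% max(1L, floor(sqrt(ncol(x))))
  trees <- vector("list", n_trees)
  n <- nrow(x)
  for (b in seq_len(n_trees)) {
    bs <- sample.int(n, n, replace = TRUE)
    trees[[b]] <- grow_tree(x[bs, , drop = FALSE], y[bs], mtry, min_node)
  }
  structure(list(trees = trees, mtry = mtry), class = "cascnet_rf")
}

#' @export
predict.cascnet_rf <- function(object, newdata, ...) {
  x <- as.matrix(newdata)
  out <- numeric(nrow(x))
  for (i in seq_len(nrow(x))) {
    out[i] <- mean(vapply(object$trees, predict_tree, numeric(1), x[i, ]))
  }
  out
}

# ---- kernel logistic machines -------------------------------------------

kernel_matrix_fn <- function(kernel, gamma, degree, coef0) {
  switch(kernel,
    linear  = function(A, B) A %*% t(B),
    poly    = function(A, B) (gamma * A %*% t(B) + coef0)^degree,
    rbf     = function(A, B) {
      d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * A %*% t(B)
      exp(-gamma * pmax(d2, 0))
    },
    sigmoid = function(A, B) tanh(gamma * A %*% t(B) + coef0),
    stop_fmt("unknown kernel: %s", kernel))
}

#' Fit a kernel logistic classifier
#'
#' L2-regularised kernel logistic regression solved by Newton-IRLS in the
#' dual: minimises cross-entropy + `1/(2C) * alpha' K alpha` with
#' `f = (K + 1) alpha` (the +1 constant kernel supplies an intercept).
#' Provides the four classic SVM kernels and emits probabilities directly.
#'
#' @param x numeric feature matrix (standardise first; see
#'   [train_models()]).
#' @param y binary labels.
#' @param kernel `"linear"`, `"poly"`, `"rbf"` or `"sigmoid"`.
#' @param C inverse regularisation strength (default 1).
#' @param gamma kernel coefficient (default `1/ncol(x)`).
#' @param degree polynomial degree (default 3).
#' @param coef0 offset for poly/sigmoid kernels (default 1).
#' @param max_iter,tol IRLS controls.
#' @return object of class `cascnet_klr`.
#' @export
klr_fit <- function(x, y, kernel = c("linear", "poly", "rbf", "sigmoid"),
                    C = 1, gamma = NULL, degree = 3, coef0 = 1,
                    max_iter = 50, tol = 1e-8) {
  kernel <- match.arg(kernel)
  x <- as.matrix(x)
  y <- as_binary(y)
  gamma <- gamma %||% (1 / ncol(x))
  kfun <- kernel_matrix_fn(kernel, gamma, degree, coef0)
  K <- kfun(x, x) + 1          # constant kernel term = unregularised-ish bias
  n <- nrow(K)
  lambda <- 1 / C
  alpha <- rep(0, n)
  f <- drop(K %*% alpha)
  for (it in seq_len(max_iter)) {
    p <- 1 / (1 + exp(-f))
    W <- pmax(p * (1 - p), 1e-6)
    # Newton step on grad = (p - y) + lambda * alpha (K factored out)
    g <- (p - y) + lambda * alpha
    H <- K * W + diag(lambda + 1e-8, n)   # W K + lambda I, row-scaled
    step <- solve(H, g)
    alpha_new <- alpha - step
    f_new <- drop(K %*% alpha_new)
    if (max(abs(f_new - f)) < tol) { alpha <- alpha_new; f <- f_new; break }
    alpha <- alpha_new; f <- f_new
  }
  structure(list(alpha = alpha, x = x, kernel = kernel, gamma = gamma,
                 degree = degree, coef0 = coef0, C = C, kfun = kfun),
            class = "cascnet_klr")
}

#' @export
predict.cascnet_klr <- function(object, newdata, ...) {
  Kt <- object$kfun(as.matrix(newdata), object$x) + 1
  drop(1 / (1 + exp(-(Kt %*% object$alpha))))
}
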