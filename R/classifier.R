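# Tremor-type discrimination protocol: stratified 3:1 split, repeated-LASSO
# stability selection, five learners tuned by inner 10-fold CV, and
# bootstrap AUC evaluation on the held-out test set.

#' Feature table for classification
#'
#' @param x subjects x features numeric matrix (no missing values after
#'   imputation).
#' @param labels binary labels, coerced to factor with levels `TD`, `ET`.
#' @param feature_set tag: `"morphology"`, `"clinical"` or `"combined"`.
#' @return object of class `feature_table`.
#' @export
feature_table <- function(x, labels,
                          feature_set = c("morphology", "clinical",
                                          "combined")) {
  feature_set <- match.arg(feature_set)
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- paste0("f", seq_len(ncol(x)))
  labels <- factor(as.character(labels))
  if (nlevels(labels) != 2) {
    stop_fmt("stratification error: labels must have exactly 2 classes (got %d)",
             nlevels(labels))
  }
  structure(list(x = x, labels = labels, features = colnames(x),
                 feature_set = feature_set), class = "feature_table")
}

#' Build a feature table from a morphometry dataset
#'
#' Extracts per-region mean thickness (morphology), clinical scores +
#' demographics (clinical), or both (combined) for the TD and ET subjects,
#' labelled by group.
#'
#' @param dataset a `morphometry_dataset`.
#' @param feature_set `"morphology"`, `"clinical"` or `"combined"`.
#' @return a [feature_table()].
#' @export
build_feature_table <- function(dataset,
                                feature_set = c("morphology", "clinical",
                                                "combined")) {
  feature_set <- match.arg(feature_set)
  meta <- dataset$subjects
  idx <- which(meta$group %in% c("TD", "ET"))
  morph <- vapply(dataset$atlas$region_names, function(r) {
    rowMeans(dataset$thickness[idx, region_vertices(dataset$atlas, r),
                               drop = FALSE])
  }, numeric(length(idx)))
  morph <- cbind(morph, as.matrix(dataset$volumes[idx, , drop = FALSE]))
  clin_cols <- intersect(c("age", "education", "MoCA", "MMSE", "HAM_A",
                           "HAM_D", "VHI"), names(meta))
  clin <- as.matrix(meta[idx, clin_cols, drop = FALSE])
  clin <- cbind(clin, sex = as.numeric(meta$sex[idx] == "M"))
  x <- switch(feature_set, morphology = morph, clinical = clin,
              combined = cbind(morph, clin))
  feature_table(x, droplevels(factor(meta$group[idx], levels = c("TD", "ET"))),
                feature_set)
}

#' Stratified train/test split
#'
#' Randomly splits subjects into train and test sets at the given ratio,
#' preserving class proportions within one subject; disjoint, exhaustive
#' and deterministic per seed.
#'
#' @param table a [feature_table()] (>= 8 subjects, both classes present).
#' @param ratio training fraction (default 0.75, i.e. 3:1).
#' @param stratified preserve class proportions (default TRUE).
#' @param seed optional RNG seed.
#' @return list with `train` and `test` feature tables and the index
#'   vectors.
#' @export
split_train_test <- function(table, ratio = 0.75, stratified = TRUE,
                             seed = NULL) {
  stopifnot(inherits(table, "feature_table"))
  n <- nrow(table$x)
  if (n < 8) stop_fmt("need >= 8 subjects to split")
  if (any(table(table$labels) == 0)) {
    stop_fmt("stratification error: both classes must be present")
  }
  local_seed(seed)
  take <- logical(n)
  if (stratified) {
    for (cl in levels(table$labels)) {
      i <- which(table$labels == cl)
      k <- round(ratio * length(i))
      take[sample(i, k)] <- TRUE
    }
  } else {
    take[sample.int(n, round(ratio * n))] <- TRUE
  }
  sub <- function(i) {
    structure(list(x = table$x[i, , drop = FALSE],
                   labels = droplevels(table$labels[i]),
                   features = table$features,
                   feature_set = table$feature_set), class = "feature_table")
  }
  list(train = sub(which(take)), test = sub(which(!take)),
       train_idx = which(take), test_idx = which(!take))
}

#' Repeated-LASSO stability selection
#'
#' Repeats 10-fold cross-validated LASSO logistic regression `n_repeats`
#' times on the training set (fresh fold assignment each repeat), recording
#' which features have nonzero coefficients at the CV-chosen penalty.
#' Selection is either the features chosen in strictly more than
#' `threshold` repeats (`count_threshold`, the default) or the top 30% by
#' selection count (`top_30pct`).
#'
#' @param train a training [feature_table()] with >= `cv_folds` subjects
#'   per class.
#' @param n_repeats LASSO repetitions (default 1000).
#' @param cv_folds folds for each `cv.glmnet` run (default 10).
#' @param threshold selection-count cut for `count_threshold` mode
#'   (default 500).
#' @param mode `"count_threshold"` or `"top_30pct"`.
#' @param seed optional RNG seed.
#' @return object of class `selection_profile`: per-feature `counts`,
#'   `selected` feature names, `threshold`, `mode`, `n_repeats`.
#' @export
lasso_stability_select <- function(train, n_repeats = 1000, cv_folds = 10,
                                   threshold = 500,
                                   mode = c("count_threshold", "top_30pct"),
                                   seed = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(train, "feature_table"))
  if (any(table(train$labels) < cv_folds)) {
    stop_fmt("need >= %d subjects per class for %d-fold CV", cv_folds,
             cv_folds)
  }
  x <- train$x
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    warn_fmt("dropping constant feature(s): %s",
             paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  x <- scale(x)
  y <- train$labels
  local_seed(seed)
  counts <- stats::setNames(integer(ncol(x)), colnames(x))
  n <- nrow(x)
  for (r in seq_len(n_repeats)) {
    foldid <- sample(rep_len(seq_len(cv_folds), n))
    fit <- glmnet::cv.glmnet(x, y, family = "binomial", alpha = 1,
                             foldid = foldid, type.measure = "deviance")
    beta <- as.matrix(glmnet::coef.glmnet(fit$glmnet.fit, s = fit$lambda.min))
    nz <- rownames(beta)[-1][beta[-1, 1] != 0]
    counts[nz] <- counts[nz] + 1L
  }
  selected <- if (mode == "count_threshold") {
    names(counts)[counts > threshold]
  } else {
    k <- ceiling(0.3 * length(counts))
    names(sort(counts, decreasing = TRUE))[seq_len(k)]
  }
  structure(list(counts = counts, selected = selected, threshold = threshold,
                 mode = mode, n_repeats = n_repeats),
            class = "selection_profile")
}

#' @export
print.selection_profile <- function(x, ...) {
  cat(sprintf("selection_profile (%s, %d repeats): %d / %d features selected\n",
              x$mode, x$n_repeats, length(x$selected), length(x$counts)))
  if (length(x$selected)) {
    cat("  ", paste(sprintf("%s (%d)", x$selected, x$counts[x$selected]),
                    collapse = ", "), "\n")
  }
  invisible(x)
}

LEARNERS <- c("RF", "SVM-linear", "SVM-poly", "SVM-rbf", "SVM-sigmoid")

#' Train the five classifiers with inner cross-validated tuning
#'
#' Trains a random forest and the four kernel machines on the selected
#' features, tuning each by inner `inner_cv`-fold cross-validated AUC over
#' a small grid: `C` in `10^(-1..2)` for the kernel machines (four
#' decades), `mtry` in `{sqrt(p), p/2}` for the forest (500 trees fixed).
#' Features are z-standardised on the training split for the kernel
#' machines and the LASSO; the forest consumes raw features.
#'
#' @param train a training [feature_table()].
#' @param selected_features non-empty character vector (e.g. from
#'   [lasso_stability_select()]).
#' @param learners subset of
#'   `c("RF", "SVM-linear", "SVM-poly", "SVM-rbf", "SVM-sigmoid")`.
#' @param inner_cv inner CV folds (default 10).
#' @param seed optional RNG seed.
#' @param n_trees forest size (default 500).
#' @return object of class `model_bundle`: fitted models, tuned settings,
#'   scaling parameters, feature names.
#' @export
train_models <- function(train, selected_features, learners = LEARNERS,
                         inner_cv = 10, seed = NULL, n_trees = 500) {
  stopifnot(inherits(train, "feature_table"))
  if (!length(selected_features)) {
    stop_fmt(paste0("configuration error: empty feature selection; ",
                    "consider mode = 'top_30pct'"))
  }
  miss <- setdiff(selected_features, colnames(train$x))
  if (length(miss)) stop_fmt("unknown feature(s): %s", paste(miss, collapse = ", "))
  learners <- match.arg(learners, LEARNERS, several.ok = TRUE)
  local_seed(seed)
  xr <- train$x[, selected_features, drop = FALSE]
  mu <- colMeans(xr); sdv <- apply(xr, 2, stats::sd)
  sdv[sdv == 0] <- 1
  xs <- scale(xr, center = mu, scale = sdv)
  y <- train$labels
  yb <- as_binary(y)
  n <- nrow(xr)

  folds <- sample(rep_len(seq_len(inner_cv), n))
  cv_auc <- function(fit_fun) {
    preds <- numeric(n)
    for (f in seq_len(inner_cv)) {
      tr <- folds != f
      if (length(unique(yb[tr])) < 2) return(NA_real_)
      m <- fit_fun(tr)
      preds[!tr] <- m(!tr)
    }
    auc(preds, yb)
  }

  models <- list(); tuned <- list()
  for (lr in learners) {
    if (lr == "RF") {
      grid <- unique(c(max(1L, floor(sqrt(ncol(xr)))),
                       max(1L, floor(ncol(xr) / 2))))
      scores <- vapply(grid, function(mt) {
        cv_auc(function(tr) {
          m <- rf_fit(xr[tr, , drop = FALSE], yb[tr],
                      n_trees = min(n_trees, 100), mtry = mt)
          function(te) predict(m, xr[te, , drop = FALSE])
        })
      }, numeric(1))
      best <- grid[which.max(scores)]
      models[[lr]] <- rf_fit(xr, yb, n_trees = n_trees, mtry = best)
      tuned[[lr]] <- list(mtry = best, n_trees = n_trees,
                          cv_auc = max(scores, na.rm = TRUE))
    } else {
      kern <- sub("SVM-", "", lr)
      grid <- 10^(-1:2)
      scores <- vapply(grid, function(C) {
        cv_auc(function(tr) {
          m <- klr_fit(xs[tr, , drop = FALSE], yb[tr], kernel = kern, C = C)
          function(te) predict(m, xs[te, , drop = FALSE])
        })
      }, numeric(1))
      best <- grid[which.max(scores)]
      models[[lr]] <- klr_fit(xs, yb, kernel = kern, C = best)
      tuned[[lr]] <- list(C = best, cv_auc = max(scores, na.rm = TRUE))
    }
  }
  structure(list(models = models, tuned = tuned, features = selected_features,
                 center = mu, scale = sdv, levels = levels(y)),
            class = "model_bundle")
}

#' Predict class probabilities from a model bundle
#' @param bundle a `model_bundle`.
#' @param table a [feature_table()].
#' @return matrix of probabilities (rows = subjects, columns = learners).
#' @export
predict_bundle <- function(bundle, table) {
  xr <- table$x[, bundle$features, drop = FALSE]
  xs <- scale(xr, center = bundle$center, scale = bundle$scale)
  out <- vapply(names(bundle$models), function(lr) {
    m <- bundle$models[[lr]]
    if (inherits(m, "cascnet_rf")) predict(m, xr) else predict(m, xs)
  }, numeric(nrow(xr)))
  if (is.null(dim(out))) out <- matrix(out, nrow = 1,
                                       dimnames = list(NULL, names(bundle$models)))
  out
}

#' Bootstrap AUC evaluation on the test set
#'
#' Computes predicted probabilities once per learner, then bootstraps the
#' test subjects `n_resamples` times, recomputing the AUC each time.
#' Resamples containing a single class are redrawn (at most 10x the
#' requested number of attempts).
#'
#' @param bundle a `model_bundle` from [train_models()].
#' @param test a non-empty test [feature_table()] with both classes.
#' @param n_resamples bootstrap resamples (default 1000).
#' @param seed optional RNG seed.
#' @return list of `model_eval` objects (one per learner): `auc_samples`,
#'   `mean_auc`, `ci` (2.5/97.5 percentiles), `point_auc`.
#' @export
evaluate_resampled_auc <- function(bundle, test, n_resamples = 1000,
                                   seed = NULL) {
  stopifnot(inherits(test, "feature_table"))
  yb <- as_binary(test$labels)
  if (length(unique(yb)) < 2) {
    stop_fmt("test set must contain both classes")
  }
  local_seed(seed)
  probs <- predict_bundle(bundle, test)
  n <- length(yb)
  idx_mat <- matrix(NA_integer_, n_resamples, n)
  attempts <- 0
  b <- 1
  while (b <= n_resamples) {
    if ((attempts <- attempts + 1) > 10 * n_resamples) {
      stop_fmt("could not draw two-class resamples within 10x attempts")
    }
    i <- sample.int(n, n, replace = TRUE)
    if (length(unique(yb[i])) < 2) next
    idx_mat[b, ] <- i
    b <- b + 1
  }
  lapply(stats::setNames(nm = colnames(probs)), function(lr) {
    s <- probs[, lr]
    samples <- apply(idx_mat, 1, function(i) auc(s[i], yb[i]))
    structure(list(model = lr, auc_samples = samples,
                   mean_auc = mean(samples),
                   ci = stats::quantile(samples, c(0.025, 0.975)),
                   point_auc = auc(s, yb)),
              class = "model_eval")
  })
}

#' @export
print.model_eval <- function(x, ...) {
  cat(sprintf("%s: AUC %.3f (95%% CI %.3f-%.3f, %d resamples)\n",
              x$model, x$mean_auc, x$ci[1], x$ci[2], length(x$auc_samples)))
  invisible(x)
}
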