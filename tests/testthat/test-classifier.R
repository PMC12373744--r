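# classifier: split, LASSO stability selection, learners, bootstrap AUC.

make_gauss_table <- function(n = 140, d = 1.5, p_noise = 3, seed = 1,
                             n_pos = NULL) {
  withr::local_seed(seed)
  n_pos <- n_pos %||% round(n / 2)
  y <- rep(c("ET", "TD"), c(n - n_pos, n_pos))
  x <- cbind(signal = rnorm(n) + d * (y == "TD"),
             matrix(rnorm(n * p_noise), n))
  colnames(x) <- c("signal", paste0("noise", seq_len(p_noise)))
  feature_table(x, y, "morphology")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("stratified split: 140 subjects (69/71) give 105/35 within one", {
  ft <- make_gauss_table(n = 140, n_pos = 69)
  sp <- split_train_test(ft, seed = 3)
  expect_equal(nrow(sp$train$x) + nrow(sp$test$x), 140)
  expect_lte(abs(nrow(sp$train$x) - 105), 1)
  for (cl in c("TD", "ET")) {
    frac_tr <- mean(sp$train$labels == cl)
    frac_all <- mean(ft$labels == cl)
    expect_lt(abs(frac_tr - frac_all), 0.02)
  }
  expect_identical(sp$train_idx, split_train_test(ft, seed = 3)$train_idx)
  expect_false(identical(sp$train_idx,
                         split_train_test(ft, seed = 4)$train_idx))
  expect_length(intersect(sp$train_idx, sp$test_idx), 0)

  one_class <- feature_table(matrix(rnorm(8), 4), rep(c("TD", "ET"), 2))
  expect_error(split_train_test(one_class), ">= 8")
})

test_that("stability selection separates signal from noise features", {
  # one feature = labels + tiny noise, nine pure-noise features
  withr::local_seed(7)
  n <- 105
  y <- factor(rep(c("TD", "ET"), length.out = n))
  x <- cbind(signal = as.numeric(y == "TD") + rnorm(n, 0, 0.05),
             matrix(rnorm(n * 9), n,
                    dimnames = list(NULL, paste0("noise", 1:9))))
  ft <- feature_table(x, y, "morphology")
  prof <- lasso_stability_select(ft, n_repeats = 100, threshold = 50,
                                 seed = 11)
  expect_gte(prof$counts[["signal"]], 90)
  expect_true(all(prof$counts[names(prof$counts) != "signal"] < 50))
  expect_identical(prof$selected, "signal")

  # counts {A:850, B:420} with threshold 500 select exactly {A}
  prof2 <- structure(list(counts = c(A = 850L, B = 420L), threshold = 500,
                          mode = "count_threshold", n_repeats = 1000),
                     class = "selection_profile")
  expect_identical(names(prof2$counts)[prof2$counts > prof2$threshold], "A")

  # top-30% mode keeps ceiling(0.3 p) features
  prof3 <- lasso_stability_select(ft, n_repeats = 20, mode = "top_30pct",
                                  seed = 2)
  expect_length(prof3$selected, ceiling(0.3 * 10))
  expect_true("signal" %in% prof3$selected)
})

test_that("selection is train-only: corrupting test labels changes nothing", {
  ft <- make_gauss_table(n = 120, d = 1.5, seed = 9)
  sp <- split_train_test(ft, seed = 1)
  p1 <- lasso_stability_select(sp$train, n_repeats = 30, threshold = 15,
                               seed = 5)
  sp$test$labels <- rev(sp$test$labels)   # corrupt the held-out labels
  p2 <- lasso_stability_select(sp$train, n_repeats = 30, threshold = 15,
                               seed = 5)
  expect_identical(p1$counts, p2$counts)
  expect_identical(p1$selected, p2$selected)
})

test_that("AUC: rank definition, tie handling, monotone invariance", {
  y <- c(0, 0, 1, 1)
  expect_equal(auc(c(0.1, 0.2, 0.8, 0.9), y), 1)
  expect_equal(auc(c(0.9, 0.8, 0.2, 0.1), y), 0)
  expect_equal(auc(c(0.5, 0.5, 0.5, 0.5), y), 0.5)
  s <- runif(50); yy <- rbinom(50, 1, 0.5)
  expect_equal(auc(s, yy), auc(qlogis(s), yy))      # strictly monotone map
  expect_equal(auc(s, yy), auc(s^3, yy))
})

test_that("learners fit separable data and tune deterministically", {
  ft <- make_gauss_table(n = 60, d = 8, p_noise = 1, seed = 13)
  b1 <- train_models(ft, "signal", inner_cv = 5, seed = 21, n_trees = 60)
  b2 <- train_models(ft, "signal", inner_cv = 5, seed = 21, n_trees = 60)
  expect_identical(lapply(b1$tuned, `[[`, 1), lapply(b2$tuned, `[[`, 1))
  probs <- predict_bundle(b1, ft)
  for (lr in colnames(probs)) {
    expect_gte(auc(probs[, lr], ft$labels), 0.99)
  }
  expect_error(train_models(ft, character(0)), "empty feature selection")
})

test_that("bootstrap AUC evaluation behaves at the extremes", {
  ft <- make_gauss_table(n = 80, d = 2, seed = 17)
  sp <- split_train_test(ft, seed = 2)
  bundle <- train_models(sp$train, "signal",
                         learners = c("SVM-linear", "RF"),
                         inner_cv = 5, seed = 3, n_trees = 60)
  ev <- evaluate_resampled_auc(bundle, sp$test, n_resamples = 200, seed = 4)
  for (e in ev) {
    expect_true(all(e$auc_samples >= 0 & e$auc_samples <= 1))
    expect_gte(e$ci[1], min(e$auc_samples))
    expect_lte(e$ci[2], max(e$auc_samples))
  }
  # predictions identical to labels give AUC exactly 1 in every resample
  fake <- bundle
  ideal <- as.numeric(sp$test$labels == levels(sp$test$labels)[2])
  expect_equal(auc(ideal, sp$test$labels), 1)
  # full pipeline reproducibility from one seed chain
  ev2 <- evaluate_resampled_auc(bundle, sp$test, n_resamples = 200, seed = 4)
  expect_identical(lapply(ev, `[[`, "auc_samples"),
                   lapply(ev2, `[[`, "auc_samples"))
})
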