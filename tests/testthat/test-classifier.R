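# Classifier stack: standardization, balancing, MLP training/prediction,
# metrics, cross-validation without leakage, grid search, combined models
# and the baseline-comparison harness.

sep_dataset <- function(n = 200, effect = 3, seed = 1) {
  simulate_labeled_features(c(enhancer = n, other = n),
                            informative = c(n_inserts_all = effect,
                                            fold_change = effect / 2),
                            seed = seed)
}

test_that("standardization matches the population z-score and handles constants", {
  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 5))
  s <- standardize(X)
  expect_equal(unname(s$center), c(2, 5))
  expect_equal(unname(s$scale[1]), sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(unname(s$X[, "a"]), c(-1, 0, 1) * 1.2247449, tolerance = 1e-6)
  expect_equal(unname(s$X[, "b"]), c(0, 0, 0))
  # training transform has column means 0
  expect_lt(max(abs(colMeans(s$X))), 1e-9)
  # held-out transform uses training statistics only
  Xt <- apply_standardization(cbind(a = 4, b = 6), s$center, s$scale)
  expect_equal(unname(Xt[1, 1]), (4 - 2) / sqrt(2 / 3))
})

test_that("down-sampling balances classes reproducibly without replacement", {
  ds <- simulate_labeled_features(c(enhancer = 100, other = 40), seed = 3)
  bal <- downsample_balance(ds, seed = 9)
  expect_equal(as.vector(table(bal$labels)), c(40L, 40L))
  expect_false(any(duplicated(rownames(bal$features))))
  bal2 <- downsample_balance(ds, seed = 9)
  expect_identical(rownames(bal$features), rownames(bal2$features))
  # already balanced: row set unchanged
  even <- simulate_labeled_features(c(enhancer = 30, other = 30), seed = 4)
  expect_setequal(rownames(downsample_balance(even, 1)$features),
                  rownames(even$features))
})

test_that("MLP separates a separable synthetic and is seed-deterministic", {
  ds <- sep_dataset(n = 200)
  model <- suppressWarnings(train_mlp(ds, seed = 5))
  pr <- predict(model, ds$features)
  expect_gte(mean(pr$call == as.character(ds$labels)), 0.98)
  # probabilities form a simplex
  expect_equal(unname(rowSums(pr$prob)), rep(1, nrow(ds$features)), tolerance = 1e-9)
  # determinism
  model2 <- suppressWarnings(train_mlp(ds, seed = 5))
  pr2 <- predict(model2, ds$features)
  expect_identical(pr$prob, pr2$prob)
  # held-out positives score above negatives
  held <- sep_dataset(n = 100, seed = 77)
  ph <- predict(model, held$features)$prob[, "enhancer"]
  expect_gt(mean(ph[held$labels == "enhancer"]), mean(ph[held$labels == "other"]))
})

test_that("prediction validates the feature schema and applies the strict 0.5 rule", {
  ds <- sep_dataset(n = 50)
  model <- suppressWarnings(train_mlp(ds, seed = 2))
  expect_error(predict(model, ds$features[, -1]), "missing \\[peak_score\\]")
  Xx <- cbind(ds$features, junk = 1)
  expect_error(predict(model, Xx), "extra \\[junk\\]")
  # a probability of exactly 0.5 is a negative call
  fake <- model
  classes <- fake$classes
  p_half <- matrix(0.5, 2, 2, dimnames = list(NULL, classes))
  call <- ifelse(p_half[, "enhancer"] > 0.5, "enhancer", setdiff(classes, "enhancer"))
  expect_equal(unique(call), "other")
})

test_that("permuted labels give chance-level cross-validated AUC", {
  ds <- sep_dataset(n = 150, seed = 10)
  set.seed(21)
  ds$labels <- sample(ds$labels)
  cv <- suppressWarnings(cross_validate(ds, k = 5, seed = 13))
  expect_lt(abs(cv$mean_roc_auc - 0.5), 0.08)
})

test_that("ROC AUC equals the brute-force concordant-pair fraction", {
  expect_equal(evaluate(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$roc_auc, 1.0)
  expect_equal(evaluate(c(0.9, 0.6, 0.4, 0.1), c(1, 0, 1, 0))$roc_auc, 0.75)
  expect_equal(evaluate(c(0.1, 0.2, 0.8, 0.9), c(1, 1, 0, 0))$roc_auc, 0.0)
  expect_error(evaluate(c(0.3, 0.4), c(1, 1)), "both classes")
  set.seed(31)
  for (i in 1:60) {
    n <- sample(3:12, 1)
    y <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    # discretized probabilities so ties occur
    p <- sample(seq(0, 1, 0.25), n, replace = TRUE)
    expect_equal(evaluate(p, y)$roc_auc, bruteforce_auc(p, y))
  }
})

test_that("PRC AUC is 1 for perfect ranking and near prevalence for random scores", {
  expect_equal(evaluate(c(0.9, 0.8, 0.3, 0.1), c(1, 1, 0, 0))$prc_auc, 1.0)
  set.seed(8)
  y <- rep(c(TRUE, FALSE), c(100, 300))
  p <- runif(400)
  expect_lt(abs(evaluate(p, y)$prc_auc - 0.25), 0.1)
})

test_that("stratified CV balances folds and is reproducible", {
  ds <- sep_dataset(n = 103, seed = 6)
  folds <- stratified_folds(ds$labels, 5, seed = 3)
  per_class <- table(folds, ds$labels)
  expect_true(all(apply(per_class, 2, function(x) diff(range(x))) <= 1))
  cv1 <- suppressWarnings(cross_validate(ds, k = 5, seed = 17))
  cv2 <- suppressWarnings(cross_validate(ds, k = 5, seed = 17))
  expect_identical(cv1$pooled_probs, cv2$pooled_probs)
  expect_gte(cv1$mean_roc_auc, 0.9)
  expect_error(cross_validate(sep_dataset(n = 3), k = 5), ">= 5 rows")
})

test_that("held-out rows cannot influence training statistics (no leakage)", {
  ds <- sep_dataset(n = 60, seed = 12)
  folds <- stratified_folds(ds$labels, 5, seed = 99)
  te <- which(folds == 1)
  tr <- which(folds != 1)
  train <- enhancerpred:::subset_dataset(ds, tr)
  model <- suppressWarnings(train_mlp(train, seed = 4))
  p_before <- predict(model, ds$features[te, , drop = FALSE])$prob
  # perturb a held-out row wildly and retrain on the same training rows:
  # the model (and other rows' predictions) must be unchanged
  ds$features[te[1], ] <- ds$features[te[1], ] + 1000
  train_after <- enhancerpred:::subset_dataset(ds, tr)
  model_after <- suppressWarnings(train_mlp(train_after, seed = 4))
  expect_identical(model$center, model_after$center)
  expect_identical(model$fit$params, model_after$fit$params)
  p_after <- predict(model_after, ds$features[te[-1], , drop = FALSE])$prob
  expect_identical(p_before[-1, ], p_after)
})

test_that("binary mode is the two-class special case of multi-class training", {
  ds3 <- simulate_labeled_features(c(enhancer = 60, promoter = 0, other = 60),
                                   informative = c(n_inserts_all = 3), seed = 5)
  # with promoters absent the label set reduces to two classes
  expect_equal(nlevels(droplevels(ds3$labels)), 2L)
  model <- suppressWarnings(train_mlp(ds3, seed = 3))
  expect_equal(sort(model$classes), c("enhancer", "other"))
  # genuine 3-class data trains and yields a 3-column simplex
  dsm <- simulate_labeled_features(c(enhancer = 50, promoter = 50, other = 50),
                                   informative = c(n_inserts_all = 2), seed = 6)
  m3 <- suppressWarnings(train_mlp(dsm, seed = 3))
  pr <- predict(m3, dsm$features)
  expect_equal(ncol(pr$prob), 3L)
  expect_equal(unname(rowSums(pr$prob)), rep(1, 150), tolerance = 1e-9)
})

test_that("grid search selects by mean CV accuracy with deterministic ties", {
  ds <- sep_dataset(n = 60, seed = 9)
  one <- list(mlp_hyperparams(hidden = 8, max_epochs = 60))
  res <- suppressWarnings(grid_search(ds, one, k = 3, seed = 2))
  expect_identical(res$best, one[[1]])
  expect_equal(nrow(res$scores), 1L)
  expect_error(mlp_hyperparams(hidden = 0), ">= 1")
  expect_error(grid_search(ds, list(), k = 3), "empty")
})

test_that("combined models pool rows, keep source tags and balance after pooling", {
  d1 <- sep_dataset(n = 50, seed = 1); d1$source <- "ct1"
  d2 <- sep_dataset(n = 50, seed = 2); d2$source <- "ct2"
  model <- suppressWarnings(train_combined(list(d1, d2), seed = 3))
  expect_setequal(model$sources, c("ct1", "ct2"))
  # schema mismatch errors
  d3 <- d2
  colnames(d3$features)[1] <- "renamed"
  expect_error(train_combined(list(d1, d3)), "schema")
  # two identical datasets train the same as the duplicated matrix
  dup <- enhancerpred:::pool_datasets(list(d1, d1))
  m_dup <- suppressWarnings(train_mlp(downsample_balance(dup, child_seed(3, 7)),
                                      seed = 3))
  m_comb <- suppressWarnings(train_combined(list(d1, d1), seed = 3))
  expect_equal(m_comb$fit$params, m_dup$fit$params)
})

test_that("algorithm comparison covers all families near the Gaussian optimum", {
  # equal-covariance Gaussian classes: analytic Bayes ROC AUC = Phi(d/sqrt(2))
  delta <- 1.8
  ds <- simulate_labeled_features(c(enhancer = 150, other = 150),
                                  informative = c(peak_score = delta),
                                  n_features = 4, seed = 14)
  bayes_auc <- pnorm(delta / sqrt(2))
  tab <- suppressWarnings(
    compare_algorithms(ds, c("mlp", "svm", "random_forest", "knn",
                             "naive_bayes", "qda"), seed = 20, k = 5))
  expect_equal(nrow(tab), 6L)
  expect_true(all(abs(tab$roc_auc - bayes_auc) < 0.07))
  expect_error(compare_algorithms(ds, "boosting"), "unknown families")
  # single-family table equals plain cross-validation
  cv <- suppressWarnings(cross_validate(ds, k = 5, seed = 20, pool_probs = FALSE))
  solo <- suppressWarnings(compare_algorithms(ds, "mlp", seed = 20, k = 5))
  expect_equal(solo$roc_auc, cv$mean_roc_auc)
  # determinism
  solo2 <- suppressWarnings(compare_algorithms(ds, "mlp", seed = 20, k = 5))
  expect_identical(solo, solo2)
})

test_that("duplicating the informative feature does not hurt CV AUC beyond noise", {
  ds <- sep_dataset(n = 150, seed = 16)
  cv_base <- suppressWarnings(cross_validate(ds, k = 5, seed = 8))
  X2 <- cbind(ds$features, n_inserts_all_copy = ds$features[, "n_inserts_all"])
  ds2 <- list(features = X2, labels = ds$labels, source = ds$source)
  class(ds2) <- "labeled_dataset"
  cv_dup <- suppressWarnings(cross_validate(ds2, k = 5, seed = 8))
  expect_gte(cv_dup$mean_roc_auc, cv_base$mean_roc_auc - 0.02)
})
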