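# Model training and evaluation: labeled datasets, per-column
# standardization, class balancing by down-sampling, the MLP bundle
# (train/predict), ROC/PRC metrics, stratified cross-validation without
# leakage, grid search, pooled "combined" models, and a harness comparing the
# MLP against five baseline algorithm families.

#' Construct a labeled dataset
#'
#' @param features data frame with a `peak_id` column plus numeric feature
#'   columns (canonically the 24 of [feature_names()], but any schema works).
#' @param labels character vector of class labels, one per row; `"excluded"`
#'   rows are dropped here and never enter training or evaluation.
#' @param source a tag identifying the origin (cell type / individual).
#' @return list of class `labeled_dataset` with `features` (numeric matrix,
#'   rownames = peak ids), `labels` (factor) and `source`.
#' @export
labeled_dataset <- function(features, labels, source = "unknown") {
  stopifnot(nrow(features) == length(labels))
  keep <- labels != "excluded"
  features <- features[keep, , drop = FALSE]
  labels <- labels[keep]
  ids <- if ("peak_id" %in% names(features)) features$peak_id else rownames(features)
  X <- as.matrix(features[, setdiff(names(features), "peak_id"), drop = FALSE])
  if (anyNA(X)) stop("labeled dataset contains missing feature values", call. = FALSE)
  rownames(X) <- ids
  ds <- list(features = X, labels = factor(labels), source = source)
  class(ds) <- "labeled_dataset"
  ds
}

subset_dataset <- function(ds, idx) {
  out <- list(features = ds$features[idx, , drop = FALSE],
              labels = droplevels(ds$labels[idx]), source = ds$source)
  class(out) <- "labeled_dataset"
  out
}

#' Per-column z-score standardization
#'
#' Centers and scales each column by its (population-denominator) mean and
#' standard deviation. Zero-variance columns get scale 1 so they map to 0.
#' Test data must be transformed with the training statistics only, via
#' [apply_standardization()].
#'
#' @param X numeric matrix.
#' @return list with `X` (standardized), `center`, `scale`.
#' @export
standardize <- function(X) {
  center <- colMeans(X)
  n <- nrow(X)
  scale <- sqrt(colMeans(sweep(X, 2, center)^2))
  scale[scale == 0 | !is.finite(scale)] <- 1
  list(X = apply_standardization(X, center, scale), center = center, scale = scale)
}

#' Apply fitted standardization statistics to new data
#' @param X numeric matrix.
#' @param center,scale statistics from [standardize()].
#' @return standardized matrix.
#' @export
apply_standardization <- function(X, center, scale) {
  sweep(sweep(X, 2, center), 2, scale, "/")
}

#' Down-sample every class to the minority-class size
#'
#' @param dataset a `labeled_dataset`.
#' @param seed integer seed; sampling is without replacement and reproducible.
#' @return a balanced `labeled_dataset`.
#' @export
downsample_balance <- function(dataset, seed = 1L) {
  tab <- table(dataset$labels)
  if (length(tab) < 2L) stop("need >= 2 classes to balance", call. = FALSE)
  if (any(tab == 0L)) stop("class with 0 rows", call. = FALSE)
  n_min <- min(tab)
  set.seed(seed)
  idx <- unlist(lapply(levels(dataset$labels), function(cl) {
    rows <- which(dataset$labels == cl)
    if (length(rows) > n_min) sample(rows, n_min) else rows
  }))
  subset_dataset(dataset, sort(idx))
}

#' Train an MLP classifier on a labeled dataset
#'
#' Standardization is fit on the training rows and embedded in the returned
#' bundle; prediction on new data reuses those statistics, so no information
#' flows from held-out rows into the model.
#'
#' @param dataset a `labeled_dataset` (>= 2 classes).
#' @param hyperparams [mlp_hyperparams()].
#' @param seed integer seed (weight initialization + validation split).
#' @param mask_to_zero optional character vector of feature names whose
#'   standardized values are set to 0 (the training mean) during training;
#'   used by single-feature importance models to keep the architecture fixed.
#' @return a `model_bundle`: weights, standardization statistics, feature and
#'   class order, seed, hyperparameters and the training-locus manifest.
#' @export
train_mlp <- function(dataset, hyperparams = mlp_hyperparams(), seed = 1L,
                      mask_to_zero = NULL) {
  if (nlevels(dataset$labels) < 2L) stop("training needs >= 2 classes", call. = FALSE)
  std <- standardize(dataset$features)
  X <- std$X
  if (!is.null(mask_to_zero)) {
    bad <- setdiff(mask_to_zero, colnames(X))
    if (length(bad)) stop(sprintf("unknown features: %s", paste(bad, collapse = ", ")),
                          call. = FALSE)
    X[, mask_to_zero] <- 0
  }
  fit <- mlp_fit(X, dataset$labels, hyperparams, seed)
  bundle <- list(fit = fit, center = std$center, scale = std$scale,
                 feature_order = colnames(dataset$features),
                 classes = fit$classes, seed = seed, hyperparams = hyperparams,
                 mask_to_zero = mask_to_zero,
                 training_loci = rownames(dataset$features),
                 sources = unique(dataset$source))
  class(bundle) <- "model_bundle"
  bundle
}

#' Predict class probabilities from a model bundle
#'
#' @param object a `model_bundle`.
#' @param newdata numeric matrix or feature data frame; columns must match the
#'   bundle's feature order (any order, but same set).
#' @param ... unused.
#' @return list with `prob` (rows sum to 1), and `call`: the hard call, where
#'   the binary enhancer call requires P(enhancer) strictly > 0.5 (a tie is a
#'   negative call); in multi-class mode the argmax class.
#' @export
predict.model_bundle <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    newdata <- as.matrix(newdata[, setdiff(names(newdata), "peak_id"), drop = FALSE])
  }
  missing <- setdiff(object$feature_order, colnames(newdata))
  extra <- setdiff(colnames(newdata), object$feature_order)
  if (length(missing) || length(extra)) {
    stop(sprintf("feature mismatch: missing [%s], extra [%s]",
                 paste(missing, collapse = ","), paste(extra, collapse = ",")),
         call. = FALSE)
  }
  X <- apply_standardization(newdata[, object$feature_order, drop = FALSE],
                             object$center, object$scale)
  if (!is.null(object$mask_to_zero)) X[, object$mask_to_zero] <- 0
  P <- mlp_prob(object$fit, X)
  call <- if ("enhancer" %in% object$classes && length(object$classes) == 2L) {
    ifelse(P[, "enhancer"] > 0.5, "enhancer",
           setdiff(object$classes, "enhancer"))
  } else {
    object$classes[max.col(P, ties.method = "first")]
  }
  list(prob = P, call = call)
}

#' Evaluation metrics for binary enhancer predictions
#'
#' ROC AUC is computed from the rank statistic (equivalent to the
#' concordant-pair / Mann-Whitney formulation, with ties counted 1/2); PRC
#' AUC uses step interpolation of precision at each recall level; accuracy
#' applies the strict > 0.5 call.
#'
#' @param probs numeric vector of P(positive class).
#' @param labels binary labels (logical, 0/1, or characters matching
#'   `positive`).
#' @param positive label value treated as positive (default `"enhancer"`).
#' @return list of class `eval_report`: `roc_auc`, `prc_auc`,
#'   `accuracy_at_0.5`, `confusion` (2x2 matrix).
#' @export
evaluate <- function(probs, labels, positive = "enhancer") {
  y <- normalize_binary_labels(labels, positive)
  if (!any(y) || all(y)) stop("AUCs undefined: need both classes present", call. = FALSE)
  report <- list(roc_auc = roc_auc(probs, y), prc_auc = prc_auc(probs, y),
                 accuracy_at_0.5 = mean((probs > 0.5) == y),
                 confusion = table(predicted = factor(probs > 0.5, c(FALSE, TRUE)),
                                   actual = factor(y, c(FALSE, TRUE))))
  class(report) <- "eval_report"
  report
}

normalize_binary_labels <- function(labels, positive) {
  if (is.logical(labels)) return(labels)
  if (is.numeric(labels)) return(labels == 1)
  as.character(labels) == positive
}

#' ROC AUC (rank / Mann-Whitney statistic)
#' @param probs scores; @param y logical labels.
#' @return AUC in [0,1].
#' @export
roc_auc <- function(probs, y) {
  r <- rank(probs)
  n_pos <- sum(y); n_neg <- sum(!y)
  (sum(r[y]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Precision-recall AUC (step interpolation)
#' @param probs scores; @param y logical labels.
#' @return area under the precision-recall curve.
#' @export
prc_auc <- function(probs, y) {
  ord <- order(probs, decreasing = TRUE)
  y <- y[ord]; probs <- probs[ord]
  tp <- cumsum(y)
  fp <- cumsum(!y)
  # collapse tied scores to single operating points
  last_of_tie <- c(probs[-1] != probs[-length(probs)], TRUE)
  tp <- tp[last_of_tie]; fp <- fp[last_of_tie]
  recall <- tp / sum(y)
  precision <- tp / (tp + fp)
  sum(diff(c(0, recall)) * precision)
}

#' Stratified k-fold cross-validation
#'
#' Folds are stratified by class with a fixed shuffle seed. Inside each
#' training fold, down-sampling to class balance and standardization are
#' refit from scratch, so no statistic ever sees a held-out row. Multi-class
#' datasets are evaluated on the enhancer-vs-rest probability.
#'
#' @param dataset a `labeled_dataset` (each class needs >= k rows).
#' @param k number of folds (default 5).
#' @param hyperparams [mlp_hyperparams()].
#' @param seed integer seed.
#' @param pool_probs also compute a single ROC/PRC from the concatenated
#'   held-out probabilities of all folds (default TRUE).
#' @param balance down-sample training folds to class balance (default TRUE).
#' @param mask_to_zero passed through to [train_mlp()].
#' @param trainer optional function(dataset, seed) -> model with a
#'   predict(model, X)$prob interface; defaults to the package MLP.
#' @return list of class `cv_report`: `folds` (per-fold eval reports),
#'   `mean_roc_auc`, `mean_prc_auc`, `mean_accuracy`, and with `pool_probs`
#'   `pooled` (eval report) plus `pooled_probs`/`pooled_labels`/`pooled_ids`.
#' @export
cross_validate <- function(dataset, k = 5L, hyperparams = mlp_hyperparams(),
                           seed = 1L, pool_probs = TRUE, balance = TRUE,
                           mask_to_zero = NULL, trainer = NULL) {
  folds <- stratified_folds(dataset$labels, k, seed)
  fold_reports <- vector("list", k)
  pooled_probs <- numeric(); pooled_labels <- character(); pooled_ids <- character()
  for (f in seq_len(k)) {
    te <- which(folds == f)
    tr <- which(folds != f)
    train <- subset_dataset(dataset, tr)
    if (balance) train <- downsample_balance(train, child_seed(seed, 100L + f))
    model <- if (is.null(trainer)) {
      train_mlp(train, hyperparams, child_seed(seed, 200L + f), mask_to_zero)
    } else {
      trainer(train, child_seed(seed, 200L + f))
    }
    pr <- stats::predict(model, dataset$features[te, , drop = FALSE])
    p_enh <- enhancer_prob(pr$prob)
    lab <- as.character(dataset$labels[te])
    fold_reports[[f]] <- evaluate(p_enh, lab)
    pooled_probs <- c(pooled_probs, p_enh)
    pooled_labels <- c(pooled_labels, lab)
    pooled_ids <- c(pooled_ids, rownames(dataset$features)[te])
  }
  out <- list(folds = fold_reports,
              mean_roc_auc = mean(vapply(fold_reports, `[[`, 0, "roc_auc")),
              mean_prc_auc = mean(vapply(fold_reports, `[[`, 0, "prc_auc")),
              mean_accuracy = mean(vapply(fold_reports, `[[`, 0, "accuracy_at_0.5")))
  if (pool_probs) {
    out$pooled <- evaluate(pooled_probs, pooled_labels)
    out$pooled_probs <- pooled_probs
    out$pooled_labels <- pooled_labels
    out$pooled_ids <- pooled_ids
  }
  class(out) <- "cv_report"
  out
}

enhancer_prob <- function(P) {
  if ("enhancer" %in% colnames(P)) P[, "enhancer"] else P[, 1]
}

#' Stratified fold assignment
#' @param labels factor of class labels.
#' @param k folds.
#' @param seed shuffle seed.
#' @return integer vector of fold ids (1..k); per-class fold sizes differ by
#'   at most 1.
#' @export
stratified_folds <- function(labels, k, seed = 1L) {
  labels <- as.factor(labels)
  if (any(table(labels) < k)) stop(sprintf("every class needs >= %d rows", k), call. = FALSE)
  folds <- integer(length(labels))
  set.seed(seed)
  for (cl in levels(labels)) {
    rows <- which(labels == cl)
    folds[rows] <- sample(rep_len(seq_len(k), length(rows)))
  }
  folds
}

#' Grid search over MLP hyperparameters
#'
#' Candidates are scored by mean cross-validated accuracy; ties are broken by
#' fewer parameters (total weight count), then by lexical order of the
#' candidate's deparsed form, so selection is deterministic.
#'
#' @param dataset a `labeled_dataset`.
#' @param grid list of [mlp_hyperparams()] candidates.
#' @param k CV folds.
#' @param seed integer seed.
#' @return list with `best` (hyperparams), `scores` (data frame: candidate,
#'   mean_accuracy, mean_roc_auc, n_params).
#' @export
grid_search <- function(dataset, grid, k = 5L, seed = 1L) {
  if (!length(grid)) stop("empty hyperparameter grid", call. = FALSE)
  n_feat <- ncol(dataset$features)
  n_cls <- nlevels(dataset$labels)
  rows <- lapply(seq_along(grid), function(i) {
    hp <- grid[[i]]
    cv <- cross_validate(dataset, k, hp, seed, pool_probs = FALSE)
    sizes <- c(n_feat, hp$hidden, n_cls)
    data.frame(candidate = paste0("hidden=", paste(hp$hidden, collapse = "x"),
                                  ",l2=", hp$l2),
               mean_accuracy = cv$mean_accuracy, mean_roc_auc = cv$mean_roc_auc,
               n_params = sum(sizes[-length(sizes)] * sizes[-1] + sizes[-1]))
  })
  scores <- do.call(rbind, rows)
  ord <- order(-scores$mean_accuracy, scores$n_params, scores$candidate)
  list(best = grid[[ord[1]]], best_index = ord[1], scores = scores)
}

#' Train a combined (pooled) model across datasets
#'
#' Rows from all datasets are concatenated (source tags retained in the
#' bundle), balanced by down-sampling after pooling, and fit as one model.
#'
#' @param datasets list of `labeled_dataset`s sharing one feature schema.
#' @param hyperparams [mlp_hyperparams()].
#' @param seed integer seed.
#' @param balance down-sample to class balance after pooling (default TRUE).
#' @return a `model_bundle` whose `sources` records the contributing tags.
#' @export
train_combined <- function(datasets, hyperparams = mlp_hyperparams(), seed = 1L,
                           balance = TRUE) {
  schemas <- lapply(datasets, function(d) colnames(d$features))
  if (length(unique(vapply(schemas, paste, "", collapse = "\r"))) != 1L) {
    stop("datasets do not share a feature schema", call. = FALSE)
  }
  pooled <- pool_datasets(datasets)
  if (balance) pooled <- downsample_balance(pooled, child_seed(seed, 7L))
  model <- train_mlp(pooled, hyperparams, seed)
  model$sources <- unlist(lapply(datasets, `[[`, "source"))
  model
}

pool_datasets <- function(datasets) {
  X <- do.call(rbind, lapply(datasets, `[[`, "features"))
  labels <- unlist(lapply(datasets, function(d) as.character(d$labels)))
  src <- unlist(lapply(seq_along(datasets), function(i) {
    rep(datasets[[i]]$source, nrow(datasets[[i]]$features))
  }))
  rownames(X) <- make.unique(rownames(X))
  ds <- list(features = X, labels = factor(labels), source = src)
  class(ds) <- "labeled_dataset"
  ds
}

#' Compare the MLP against baseline algorithm families
#'
#' Runs stratified cross-validation for each requested family and tabulates
#' ROC AUC, PRC AUC and accuracy. The MLP is this package's implementation;
#' baselines use the established implementations (e1071 SVM and naive Bayes,
#' randomForest, class::knn, MASS::qda). Per-family hyperparameters may be
#' grid-searched by supplying a list of candidates in `grids`.
#'
#' @param dataset a `labeled_dataset` (binary).
#' @param families subset of mlp/svm/random_forest/knn/naive_bayes/qda.
#' @param seed integer seed.
#' @param k CV folds.
#' @param grids optional named list; `grids$mlp` is a list of
#'   [mlp_hyperparams()] candidates selected by [grid_search()].
#' @return data frame: family, roc_auc, prc_auc, accuracy (CV means).
#' @export
compare_algorithms <- function(dataset,
                               families = c("mlp", "svm", "random_forest",
                                            "knn", "naive_bayes", "qda"),
                               seed = 1L, k = 5L, grids = NULL) {
  known <- c("mlp", "svm", "random_forest", "knn", "naive_bayes", "qda")
  bad <- setdiff(families, known)
  if (length(bad)) stop(sprintf("unknown families: %s", paste(bad, collapse = ", ")),
                        call. = FALSE)
  rows <- lapply(families, function(fam) {
    if (fam == "mlp") {
      hp <- mlp_hyperparams()
      if (!is.null(grids$mlp)) hp <- grid_search(dataset, grids$mlp, k, seed)$best
      cv <- cross_validate(dataset, k, hp, seed, pool_probs = FALSE)
    } else {
      cv <- cross_validate(dataset, k, seed = seed, pool_probs = FALSE,
                           trainer = baseline_trainer(fam, seed))
    }
    data.frame(family = fam, roc_auc = cv$mean_roc_auc, prc_auc = cv$mean_prc_auc,
               accuracy = cv$mean_accuracy, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Wrap a baseline family in the trainer/predict interface used by
# cross_validate: models carry their own standardization where they need it.
baseline_trainer <- function(family, seed) {
  force(family); force(seed)
  function(train, fold_seed) {
    std <- standardize(train$features)
    y <- droplevels(train$labels)
    set.seed(fold_seed)
    fit <- switch(family,
      svm = e1071::svm(std$X, y, kernel = "radial", probability = TRUE),
      random_forest = randomForest::randomForest(std$X, y, ntree = 200),
      naive_bayes = e1071::naiveBayes(std$X, y),
      qda = MASS::qda(std$X, grouping = y),
      knn = list(X = std$X, y = y, k = 15L)
    )
    obj <- list(family = family, fit = fit, center = std$center, scale = std$scale,
                classes = levels(y))
    class(obj) <- "baseline_model"
    obj
  }
}

#' @export
predict.baseline_model <- function(object, newdata, ...) {
  X <- apply_standardization(as.matrix(newdata), object$center, object$scale)
  P <- switch(object$family,
    svm = {
      pr <- stats::predict(object$fit, X, probability = TRUE)
      attr(pr, "probabilities")[, object$classes, drop = FALSE]
    },
    random_forest = stats::predict(object$fit, X, type = "prob"),
    naive_bayes = stats::predict(object$fit, X, type = "raw"),
    qda = stats::predict(object$fit, X)$posterior,
    knn = {
      pr <- class::knn(object$fit$X, X, object$fit$y, k = object$fit$k, prob = TRUE)
      win <- attr(pr, "prob")
      p1 <- ifelse(pr == object$classes[1], win, 1 - win)
      cbind(p1, 1 - p1, deparse.level = 0)
    })
  colnames(P) <- object$classes
  list(prob = P, call = object$classes[max.col(P, ties.method = "first")])
}
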