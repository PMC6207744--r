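# Feature importance: single-feature masking models and greedy backward
# elimination, both evaluated by cross-validation with pooled held-out
# probabilities.

#' Single-feature model performance by zero-masking
#'
#' Trains models in which every column except the selected feature is set to
#' zero after standardization (zero = the training mean), so the network
#' architecture is identical across features. Evaluated by k-fold CV ROC AUC
#' and, optionally, on external evaluation contexts (held-out datasets from
#' other cell types).
#'
#' @param dataset a `labeled_dataset`.
#' @param feature feature name to keep unmasked.
#' @param hyperparams [mlp_hyperparams()].
#' @param seed integer seed.
#' @param eval_contexts optional named list of `labeled_dataset`s; for each, a
#'   model trained on the full `dataset` (masked the same way) is evaluated.
#' @param k CV folds.
#' @return named numeric vector: `cv` ROC AUC plus one entry per context.
#' @export
single_feature_auc <- function(dataset, feature, hyperparams = mlp_hyperparams(),
                               seed = 1L, eval_contexts = list(), k = 5L) {
  all_feats <- colnames(dataset$features)
  if (!feature %in% all_feats) stop(sprintf("unknown feature: %s", feature), call. = FALSE)
  mask <- setdiff(all_feats, feature)
  cv <- cross_validate(dataset, k, hyperparams, seed, pool_probs = TRUE,
                       mask_to_zero = mask)
  out <- c(cv = cv$pooled$roc_auc)
  if (length(eval_contexts)) {
    bal <- downsample_balance(dataset, child_seed(seed, 3L))
    model <- train_mlp(bal, hyperparams, seed, mask_to_zero = mask)
    for (nm in names(eval_contexts)) {
      ctx <- eval_contexts[[nm]]
      pr <- stats::predict(model, ctx$features)
      out[nm] <- evaluate(enhancer_prob(pr$prob), as.character(ctx$labels))$roc_auc
    }
  }
  out
}

#' Greedy backward-elimination feature ranking
#'
#' Starting from all features, each round drops the feature whose removal
#' yields the highest pooled-probability CV ROC AUC among the candidates
#' (i.e. the feature the model misses least), retraining the full pipeline
#' (balancing + standardization + MLP) for every candidate. The removal order
#' ranks features least important first; the final remaining feature is the
#' most predictive. Ties between candidates are broken by the canonical
#' column order.
#'
#' @param dataset a `labeled_dataset` (>= 2 features).
#' @param hyperparams [mlp_hyperparams()].
#' @param seed integer seed.
#' @param k CV folds.
#' @return list of class `importance_report`: `removal_order` (character,
#'   least -> most important; a permutation of the feature names),
#'   `auc_trace` (pooled ROC AUC after each removal, same length), and
#'   `models_trained` (per-round candidate count, for audit).
#' @export
backward_elimination <- function(dataset, hyperparams = mlp_hyperparams(),
                                 seed = 1L, k = 5L) {
  feats <- colnames(dataset$features)
  if (length(feats) < 2L) stop("backward elimination needs >= 2 features", call. = FALSE)
  remaining <- feats
  removal_order <- character()
  auc_trace <- numeric()
  models_trained <- integer()
  round_i <- 0L
  while (length(remaining) >= 1L) {
    round_i <- round_i + 1L
    if (length(remaining) == 1L) {
      # score the final single-feature model, then finish
      cv <- cross_validate(dataset, k, hyperparams, child_seed(seed, round_i),
                           pool_probs = TRUE,
                           mask_to_zero = setdiff(feats, remaining))
      removal_order <- c(removal_order, remaining)
      auc_trace <- c(auc_trace, cv$pooled$roc_auc)
      models_trained <- c(models_trained, 1L)
      break
    }
    scores <- vapply(remaining, function(cand) {
      keep <- setdiff(remaining, cand)
      cv <- cross_validate(dataset, k, hyperparams, child_seed(seed, round_i),
                           pool_probs = TRUE, mask_to_zero = setdiff(feats, keep))
      cv$pooled$roc_auc
    }, 0)
    best <- which(scores == max(scores))[1]  # ties: first in canonical order
    removal_order <- c(removal_order, remaining[best])
    auc_trace <- c(auc_trace, scores[best])
    models_trained <- c(models_trained, length(remaining))
    remaining <- remaining[-best]
  }
  out <- list(removal_order = removal_order, auc_trace = auc_trace,
              models_trained = models_trained)
  class(out) <- "importance_report"
  out
}
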