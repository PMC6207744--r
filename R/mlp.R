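# Native multilayer perceptron: fully-connected network with ReLU hidden
# layers and a softmax output, trained by full-batch Adam on the multinomial
# cross-entropy with L2 weight decay and optional early stopping on a
# held-out validation split. Everything is plain matrix algebra so training
# a few hundred rows x a few dozen features takes milliseconds.

#' MLP hyperparameter set
#'
#' @param hidden integer vector of hidden-layer sizes (default one layer of 16).
#' @param l2 L2 penalty on weights (default 1e-4).
#' @param max_epochs maximum training epochs (default 300).
#' @param learning_rate Adam step size (default 0.01).
#' @param validation_fraction fraction of training rows held out for early
#'   stopping (default 0.1; 0 disables early stopping).
#' @param patience epochs without validation improvement before stopping
#'   (default 25).
#' @param one_hot expand the categorical location codes to one-hot columns at
#'   fit time (default FALSE, keeping the 24-column representation).
#' @return a list of class `mlp_hyperparams`.
#' @export
mlp_hyperparams <- function(hidden = 16L, l2 = 1e-4, max_epochs = 300L,
                            learning_rate = 0.01, validation_fraction = 0.1,
                            patience = 25L, one_hot = FALSE) {
  if (any(hidden < 1L)) stop("hidden layer sizes must be >= 1", call. = FALSE)
  structure(list(hidden = as.integer(hidden), l2 = l2,
                 max_epochs = as.integer(max_epochs),
                 learning_rate = learning_rate,
                 validation_fraction = validation_fraction,
                 patience = as.integer(patience), one_hot = isTRUE(one_hot)),
            class = "mlp_hyperparams")
}

mlp_init <- function(sizes, seed) {
  set.seed(seed)
  W <- list(); b <- list()
  for (i in seq_len(length(sizes) - 1L)) {
    # He initialization, suited to ReLU units
    W[[i]] <- matrix(stats::rnorm(sizes[i] * sizes[i + 1L], sd = sqrt(2 / sizes[i])),
                     sizes[i], sizes[i + 1L])
    b[[i]] <- rep(0, sizes[i + 1L])
  }
  list(W = W, b = b)
}

mlp_forward <- function(params, X) {
  L <- length(params$W)
  A <- list(X)
  for (i in seq_len(L)) {
    Z <- A[[i]] %*% params$W[[i]]
    Z <- sweep(Z, 2, params$b[[i]], "+")
    A[[i + 1L]] <- if (i < L) pmax(Z, 0) else softmax_rows(Z)
  }
  A
}

softmax_rows <- function(Z) {
  Z <- Z - apply(Z, 1, max)
  E <- exp(Z)
  E / rowSums(E)
}

mlp_loss <- function(P, Y, params, l2) {
  ce <- -mean(rowSums(Y * log(pmax(P, 1e-12))))
  ce + l2 * sum(vapply(params$W, function(w) sum(w^2), 0)) / 2
}

# One full-batch gradient step (Adam). Y is a one-hot matrix.
mlp_grad <- function(params, A, Y, l2) {
  L <- length(params$W)
  n <- nrow(Y)
  dW <- vector("list", L); db <- vector("list", L)
  delta <- (A[[L + 1L]] - Y) / n
  for (i in L:1) {
    dW[[i]] <- crossprod(A[[i]], delta) + l2 * params$W[[i]]
    db[[i]] <- colSums(delta)
    if (i > 1L) delta <- (delta %*% t(params$W[[i]])) * (A[[i]] > 0)
  }
  list(dW = dW, db = db)
}

#' Fit the MLP on a standardized matrix (internal core)
#'
#' @param X numeric matrix (rows = samples), already standardized.
#' @param y factor of class labels.
#' @param hyperparams [mlp_hyperparams()].
#' @param seed integer seed controlling initialization and the validation split.
#' @return list with weights, class levels and training diagnostics.
#' @keywords internal
mlp_fit <- function(X, y, hyperparams = mlp_hyperparams(), seed = 1L) {
  stopifnot(is.factor(y), nrow(X) == length(y))
  classes <- levels(y)
  Y <- stats::model.matrix(~ y - 1)
  colnames(Y) <- classes
  sizes <- c(ncol(X), hyperparams$hidden, length(classes))
  params <- mlp_init(sizes, seed)

  idx <- seq_len(nrow(X))
  val_idx <- integer()
  if (hyperparams$validation_fraction > 0 && nrow(X) >= 20L) {
    set.seed(child_seed(seed, 1L))
    n_val <- max(2L, floor(hyperparams$validation_fraction * nrow(X)))
    val_idx <- sample(idx, n_val)
  }
  tr_idx <- setdiff(idx, val_idx)
  Xtr <- X[tr_idx, , drop = FALSE]; Ytr <- Y[tr_idx, , drop = FALSE]
  Xval <- X[val_idx, , drop = FALSE]; Yval <- Y[val_idx, , drop = FALSE]

  # Adam state
  m <- lapply(params$W, function(w) w * 0); v <- m
  mb <- lapply(params$b, function(b) b * 0); vb <- mb
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  lr <- hyperparams$learning_rate
  best <- list(loss = Inf, params = params, epoch = 0L)
  stall <- 0L
  converged <- FALSE
  for (t in seq_len(hyperparams$max_epochs)) {
    A <- mlp_forward(params, Xtr)
    g <- mlp_grad(params, A, Ytr, hyperparams$l2)
    for (i in seq_along(params$W)) {
      m[[i]] <- beta1 * m[[i]] + (1 - beta1) * g$dW[[i]]
      v[[i]] <- beta2 * v[[i]] + (1 - beta2) * g$dW[[i]]^2
      mb[[i]] <- beta1 * mb[[i]] + (1 - beta1) * g$db[[i]]
      vb[[i]] <- beta2 * vb[[i]] + (1 - beta2) * g$db[[i]]^2
      mh <- m[[i]] / (1 - beta1^t); vh <- v[[i]] / (1 - beta2^t)
      mbh <- mb[[i]] / (1 - beta1^t); vbh <- vb[[i]] / (1 - beta2^t)
      params$W[[i]] <- params$W[[i]] - lr * mh / (sqrt(vh) + eps)
      params$b[[i]] <- params$b[[i]] - lr * mbh / (sqrt(vbh) + eps)
    }
    if (length(val_idx)) {
      Pv <- mlp_forward(params, Xval)[[length(params$W) + 1L]]
      vloss <- mlp_loss(Pv, Yval, params, hyperparams$l2)
      if (vloss < best$loss - 1e-6) {
        best <- list(loss = vloss, params = params, epoch = t)
        stall <- 0L
      } else {
        stall <- stall + 1L
        if (stall >= hyperparams$patience) { converged <- TRUE; break }
      }
    }
  }
  if (length(val_idx)) params <- best$params
  if (!converged && length(val_idx) && best$epoch == hyperparams$max_epochs) {
    warning("MLP training hit max_epochs without validation plateau", call. = FALSE)
  }
  list(params = params, classes = classes, sizes = sizes, seed = seed,
       epochs_run = if (length(val_idx)) best$epoch else hyperparams$max_epochs)
}

mlp_prob <- function(fit, X) {
  P <- mlp_forward(fit$params, X)[[length(fit$params$W) + 1L]]
  colnames(P) <- fit$classes
  P
}
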