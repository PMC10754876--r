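# Training (Adam + binary cross-entropy, early stopping on validation AUC
# with best-weight restoration), ranking metrics, and DeLong's test for
# correlated ROC curves.

#' Training configuration
#'
#' @param learning_rate Adam step size. Default 1e-3.
#' @param batch_size Minibatch size. Default 64.
#' @param max_epochs Maximum number of epochs. Default 1000.
#' @param early_stopping_patience Epochs without validation-AUC improvement
#'   before stopping (0 disables early stopping). Default 50.
#' @param seed Integer seed controlling shuffling, dropout and augmentation.
#' @param augmentation An [augmentation_config()] applied to training batches
#'   only, or `NULL` for none.
#' @return A `training_config` list.
#' @export
training_config <- function(learning_rate = 1e-3, batch_size = 64L,
                            max_epochs = 1000L, early_stopping_patience = 50L,
                            seed = 1L, augmentation = NULL) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            early_stopping_patience >= 0)
  if (!is.null(augmentation)) stopifnot(inherits(augmentation,
                                                 "augmentation_config"))
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 early_stopping_patience = as.integer(early_stopping_patience),
                 seed = as.integer(seed), augmentation = augmentation),
            class = "training_config")
}

# one batch of signal augmentation: one random operator order per batch,
# per-sample operator randomness (x is [B, 101, 9])
augment_signal_batch <- function(x, config, rng) {
  ord <- draw_augmentation_order(config, rng)
  if (!length(ord)) return(x)
  for (b in seq_len(dim(x)[1])) {
    cy <- gait_cycle(x[b, , ])
    x[b, , ] <- unclass(compose_augmentations(cy, config, rng, order = ord))
  }
  x
}

bce_loss <- function(p, y) {
  eps <- 1e-12
  -mean(y * log(p + eps) + (1 - y) * log(1 - p + eps))
}

#' Train a classifier
#'
#' Adam optimization of binary cross-entropy on minibatches, with per-epoch
#' validation AUC, optional early stopping, and restoration of the weights
#' from the best-validation-AUC epoch. Training batches are optionally
#' augmented (validation inputs never are). Fully reproducible from
#' `config$seed`.
#'
#' @param model A trainable `nn_model`.
#' @param x_train,y_train Training inputs (`[B, 101, 9]` signal array) and
#'   0/1 labels.
#' @param x_val,y_val Validation inputs and labels.
#' @param config A [training_config()].
#' @param transform_fn Optional function mapping a raw `[B, 101, 9]` batch to
#'   the model's input layout (e.g. flattening for the MLP or spectrum
#'   encoding for image models), applied after augmentation.
#' @return List: `model` (best weights), `history` (data frame of per-epoch
#'   train loss and validation AUC), `epoch_of_convergence` (epoch of the
#'   best validation AUC), `val_auc`.
#' @export
train_model <- function(model, x_train, y_train, x_val, y_val, config,
                        transform_fn = NULL) {
  stopifnot(inherits(model, "nn_model"), inherits(config, "training_config"))
  n <- dim(x_train)[1]
  if (n < 1 || length(y_train) != n) stop("bad training set", call. = FALSE)
  if (length(unique(y_train)) < 2L) {
    stop("training set must contain both classes", call. = FALSE)
  }
  rng <- local_rng(config$seed)
  opt <- adam_state()
  xv <- if (is.null(transform_fn)) x_val else transform_fn(x_val)
  best_auc <- -Inf; best_layers <- NULL; best_epoch <- 0L; wait <- 0L
  history <- list()
  for (epoch in seq_len(config$max_epochs)) {
    idx <- rng$sample(n)
    losses <- numeric(0)
    for (s in seq(1L, n, by = config$batch_size)) {
      e <- min(n, s + config$batch_size - 1L)
      bidx <- idx[s:e]
      xb <- x_train[bidx, , , drop = FALSE]
      if (!is.null(config$augmentation)) {
        xb <- augment_signal_batch(xb, config$augmentation, rng)
      }
      if (!is.null(transform_fn)) xb <- transform_fn(xb)
      yb <- y_train[bidx]
      fw <- model_forward(model, xb, training = TRUE, rng = rng)
      model <- fw$model
      p <- stats::plogis(as.vector(fw$out))
      loss <- bce_loss(p, yb)
      if (!is.finite(loss)) {
        stop("non-finite training loss at epoch ", epoch, call. = FALSE)
      }
      losses <- c(losses, loss)
      dz <- matrix((p - yb) / length(yb), ncol = 1L)
      model <- model_backward(model, dz)$model
      model <- adam_step(model, opt, config$learning_rate)
    }
    # a degenerate (single-class) validation split cannot rank: score 0.5
    val_auc <- if (length(unique(y_val)) < 2L) 0.5 else
      auc_mw(y_val, predict_model(model, xv))
    history[[epoch]] <- data.frame(epoch = epoch,
                                   train_loss = mean(losses),
                                   val_auc = val_auc)
    if (val_auc > best_auc) {
      best_auc <- val_auc
      best_layers <- model$layers
      best_epoch <- epoch
      wait <- 0L
    } else {
      wait <- wait + 1L
      if (config$early_stopping_patience > 0L &&
          wait >= config$early_stopping_patience) break
    }
  }
  if (!is.null(best_layers)) model$layers <- best_layers
  list(model = model, history = do.call(rbind, history),
       epoch_of_convergence = best_epoch, val_auc = best_auc)
}

#' Mann-Whitney AUC
#'
#' Probability that a uniformly random positive example outranks a uniformly
#' random negative one, ties counting one half (the rank-sum formulation;
#' identical to the area under the ROC curve).
#'
#' @param labels 0/1 vector with both classes present.
#' @param scores Real-valued scores, higher = more positive.
#' @return AUC in `[0, 1]`.
#' @export
auc_mw <- function(labels, scores) {
  check_binary(labels, scores)
  r <- rank(scores)
  n_pos <- sum(labels == 1)
  n_neg <- sum(labels == 0)
  (sum(r[labels == 1]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

check_binary <- function(labels, scores) {
  if (length(labels) != length(scores)) {
    stop("labels and scores must have equal length", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1", call. = FALSE)
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present", call. = FALSE)
  }
  invisible(TRUE)
}

#' Classification accuracy at a threshold
#'
#' @param labels 0/1 vector.
#' @param scores Real scores.
#' @param threshold Scores at or above it predict class 1. Default 0.5.
#' @return Fraction of correct predictions.
#' @export
accuracy_at <- function(labels, scores, threshold = 0.5) {
  if (!length(labels) || length(labels) != length(scores)) {
    stop("labels and scores must be non-empty and of equal length",
         call. = FALSE)
  }
  mean(as.integer(scores >= threshold) == labels)
}

#' ROC curve points
#'
#' False-positive / true-positive rates over all distinct score thresholds,
#' from (0,0) to (1,1). The trapezoidal area under the returned polyline
#' equals [auc_mw()] exactly.
#'
#' @inheritParams auc_mw
#' @return Data frame with columns `fpr`, `tpr`, monotone nondecreasing.
#' @export
roc_points <- function(labels, scores) {
  check_binary(labels, scores)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  n_pos <- sum(y == 1); n_neg <- sum(y == 0)
  tp <- cumsum(y == 1); fp <- cumsum(y == 0)
  keep <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tied block
  data.frame(fpr = c(0, fp[keep] / n_neg), tpr = c(0, tp[keep] / n_pos))
}

trapezoid_area <- function(x, y) {
  sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
}

#' Evaluate a trained model on a labelled set
#'
#' @param model A trained `nn_model`.
#' @param x Inputs (raw `[B, 101, 9]` if `transform_fn` given, else the
#'   model's layout).
#' @param y 0/1 labels.
#' @param transform_fn Optional input transform (as in [train_model()]).
#' @return List: `auc`, `accuracy`, `roc` (data frame of fpr/tpr points),
#'   `scores`.
#' @export
evaluate_model <- function(model, x, y, transform_fn = NULL) {
  if (!is.null(transform_fn)) x <- transform_fn(x)
  p <- predict_model(model, x)
  list(auc = auc_mw(y, p), accuracy = accuracy_at(y, p),
       roc = roc_points(y, p), scores = p)
}

# DeLong structural components: for each positive, the fraction of negatives
# it outranks (ties = 1/2), and symmetrically for negatives
delong_components <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  cmp <- outer(pos, neg, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(cmp), v01 = colMeans(cmp),
       auc = mean(cmp))
}

#' DeLong variance of one AUC
#'
#' Nonparametric variance estimate of a single Mann-Whitney AUC from the
#' DeLong structural components.
#'
#' @inheritParams auc_mw
#' @return Non-negative variance.
#' @export
delong_auc_variance <- function(labels, scores) {
  check_binary(labels, scores)
  cp <- delong_components(labels, scores)
  stats::var(cp$v10) / length(cp$v10) + stats::var(cp$v01) / length(cp$v01)
}

#' DeLong's test for two correlated ROC curves
#'
#' Compares the AUCs of two score vectors computed on the same examples.
#' Per-example structural components give the 2 x 2 covariance of the paired
#' AUCs; the test statistic is `z = (auc_a - auc_b) / sqrt(var_diff)` with a
#' two-sided normal p-value. When the scores are identical (variance of the
#' difference 0 with equal AUCs) the test degenerates to z = 0, p = 1.
#'
#' @param labels 0/1 vector, both classes present.
#' @param scores_a,scores_b Score vectors of the two models on the same
#'   examples.
#' @return A `delong_result` list: `auc_a`, `auc_b`,
#'   `variance_of_difference`, `z_statistic`, `p_value`.
#' @export
delong_test <- function(labels, scores_a, scores_b) {
  check_binary(labels, scores_a)
  if (length(scores_b) != length(labels)) {
    stop("scores_b length mismatch", call. = FALSE)
  }
  ca <- delong_components(labels, scores_a)
  cb <- delong_components(labels, scores_b)
  n_pos <- length(ca$v10); n_neg <- length(ca$v01)
  v10d <- ca$v10 - cb$v10
  v01d <- ca$v01 - cb$v01
  var_diff <- stats::var(v10d) / n_pos + stats::var(v01d) / n_neg
  d <- ca$auc - cb$auc
  if (var_diff <= 0) {
    z <- if (d == 0) 0 else sign(d) * Inf
  } else {
    z <- d / sqrt(var_diff)
  }
  p <- 2 * stats::pnorm(-abs(z))
  structure(list(auc_a = ca$auc, auc_b = cb$auc,
                 variance_of_difference = max(var_diff, 0),
                 z_statistic = z, p_value = p),
            class = "delong_result")
}

#' @export
print.delong_result <- function(x, ...) {
  cat(sprintf("<delong_result> AUC %.4f vs %.4f, z = %.3f, p = %.3g\n",
              x$auc_a, x$auc_b, x$z_statistic, x$p_value))
  invisible(x)
}
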