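# Training loop, checkpointing on best validation accuracy, the accuracy
# metrics, and repeated-gesture cross-validation.

#' Training configuration
#'
#' Defaults follow the reference setup: Adam, learning rate 0.001, 50
#' epochs, categorical cross-entropy, checkpoint the epoch with the highest
#' validation accuracy.  Batch size 128 is a package default (configurable).
#'
#' @param learning_rate Adam learning rate (default 0.001).
#' @param epochs training epochs (default 50).
#' @param batch_size minibatch size (default 128).
#' @param seed RNG seed for shuffling and dropout.
#' @param verbose print one line per epoch.
#' @return a `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, epochs = 50L,
                         batch_size = 128L, seed = 1L, verbose = FALSE) {
  if (learning_rate < 0) stopf("learning_rate must be >= 0")
  if (!is_count(epochs)) stopf("epochs must be >= 1")
  structure(list(learning_rate = learning_rate, epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = seed,
                 verbose = isTRUE(verbose)),
            class = "train_config")
}

#' Per-trial classification accuracy
#'
#' The ratio of correctly classified gesture fragments to the total number
#' of fragments tested.
#'
#' @param predictions predicted class labels.
#' @param labels true class labels.
#' @return accuracy in `[0, 1]`.
#' @export
accuracy <- function(predictions, labels) {
  if (length(predictions) == 0L) stopf("empty prediction set")
  if (length(predictions) != length(labels))
    stopf("predictions and labels differ in length")
  mean(predictions == labels)
}

#' Overall accuracy across subjects
#'
#' The unweighted mean of per-subject accuracies.
#'
#' @param acc_per_subject numeric vector of per-subject accuracies.
#' @return overall accuracy OA.
#' @export
overall_accuracy <- function(acc_per_subject) {
  if (length(acc_per_subject) == 0L) stopf("need at least one subject")
  mean(acc_per_subject)
}

#' Train the network
#'
#' Minibatch Adam on categorical cross-entropy.  Gesture class IDs are
#' remapped to a contiguous internal coding (the mapping is returned).  The
#' returned model carries the weights of the epoch with the highest
#' validation accuracy, not the final epoch.
#'
#' @param model a [build_model()] network.
#' @param train_set,val_set [fragment_set()]s with disjoint fragments.
#' @param cfg a [train_config()].
#' @return a `semg_fit`: list with the fitted `model`, per-epoch `history`
#'   data frame, `best_epoch`, `best_val_acc`, and the label `classes`
#'   mapping.
#' @export
train <- function(model, train_set, val_set, cfg = train_config()) {
  stopifnot(inherits(model, "semg_model"), inherits(train_set, "fragment_set"),
            inherits(val_set, "fragment_set"))
  classes <- sort(unique(train_set$label))
  if (length(classes) != model$cfg$n_classes)
    stopf("training data has %d classes, model was built for %d",
          length(classes), model$cfg$n_classes)
  missing_val <- setdiff(unique(val_set$label), classes)
  if (length(missing_val) > 0L)
    warnf("validation class(es) %s absent from training data",
          paste(missing_val, collapse = ", "))
  y_train <- match(train_set$label, classes)
  y_val <- match(val_set$label, classes)
  n <- length(train_set)
  opt <- adam_new(model$param_layers, lr = cfg$learning_rate)
  hist <- data.frame(epoch = integer(0), train_loss = numeric(0),
                     train_acc = numeric(0), val_loss = numeric(0),
                     val_acc = numeric(0))
  best <- list(val_acc = -Inf, epoch = 0L, snaps = snapshot_params(model))
  with_seed(cfg$seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(n)
      losses <- accs <- numeric(0)
      at <- 1L
      while (at <= n) {
        idx <- ord[at:min(n, at + cfg$batch_size - 1L)]
        xb <- train_set$emg[idx, , , drop = FALSE]
        dim(xb) <- c(dim(xb), 1L)
        logits <- forward_model(model, xb, training = TRUE)
        sm <- softmax_xent(logits, y_train[idx])
        backward_model(model, sm$dlogits)
        if (cfg$learning_rate > 0) opt$step()
        losses <- c(losses, sm$loss)
        accs <- c(accs, mean(max.col(sm$probs) == y_train[idx]))
        at <- at + cfg$batch_size
      }
      vp <- predict_probs(model, val_set)
      val_pred <- max.col(vp)
      # classes absent from training can never be predicted: they count as
      # misclassified and contribute no likelihood term
      ok <- !is.na(y_val)
      val_acc <- mean(ok & val_pred == y_val)
      val_loss <- if (any(ok))
        -mean(log(vp[cbind(which(ok), y_val[ok])] + 1e-12)) else NA_real_
      hist[ep, ] <- list(ep, mean(losses), mean(accs), val_loss, val_acc)
      if (val_acc > best$val_acc) {
        best <- list(val_acc = val_acc, epoch = ep,
                     snaps = snapshot_params(model))
      }
      if (cfg$verbose)
        message(sprintf("epoch %3d  loss %.4f  train acc %.3f  val acc %.3f",
                        ep, mean(losses), mean(accs), val_acc))
    }
  })
  restore_params(model, best$snaps)
  structure(list(model = model, history = hist, best_epoch = best$epoch,
                 best_val_acc = best$val_acc, classes = classes),
            class = "semg_fit")
}

#' @export
print.semg_fit <- function(x, ...) {
  cat(sprintf("<semg_fit> %d epochs, best validation accuracy %.3f at epoch %d\n",
              nrow(x$history), x$best_val_acc, x$best_epoch))
  invisible(x)
}

#' Predict gesture labels
#'
#' @param object a `semg_fit` from [train()].
#' @param newdata a [fragment_set()] or `N x T x E` array.
#' @param ... unused.
#' @return integer vector of predicted gesture class labels (original
#'   coding).
#' @export
predict.semg_fit <- function(object, newdata, ...) {
  p <- predict_probs(object$model, newdata)
  object$classes[max.col(p)]
}

#' Evaluate a fitted model on a test fragment set
#'
#' Computes per-subject accuracy, the overall accuracy (unweighted mean over
#' subjects), the confusion matrix and per-class accuracies.
#'
#' @param fit a `semg_fit`.
#' @param test_set a [fragment_set()].
#' @param fold_id optional fold identifier carried into the result.
#' @return an `eval_result`: list with `acc_per_subject`, `OA`, `confusion`
#'   (true classes in rows), `per_class_acc`, `n_test`, `fold_id`.
#' @export
evaluate <- function(fit, test_set, fold_id = NA_integer_) {
  stopifnot(inherits(fit, "semg_fit"), inherits(test_set, "fragment_set"))
  pred <- predict(fit, test_set)
  truth <- test_set$label
  subj <- test_set$subject
  acc_per_subject <- vapply(split(pred == truth, subj), mean, numeric(1))
  lev <- sort(unique(c(truth, fit$classes)))
  confusion <- table(factor(truth, lev), factor(pred, lev))
  per_class <- diag(confusion) / pmax(1L, rowSums(confusion))
  structure(list(acc_per_subject = acc_per_subject,
                 OA = overall_accuracy(acc_per_subject),
                 confusion = confusion, per_class_acc = per_class,
                 n_test = length(truth), fold_id = fold_id),
            class = "eval_result")
}

#' @export
print.eval_result <- function(x, ...) {
  cat(sprintf("<eval_result>%s OA %.3f over %d subject(s), %d test fragments\n",
              if (is.na(x$fold_id)) "" else sprintf(" fold %d:", x$fold_id),
              x$OA, length(x$acc_per_subject), x$n_test))
  invisible(x)
}

#' Repeated-gesture cross-validation
#'
#' One experiment per fold of [make_folds()]: a fresh network is trained on
#' the fold's training fragments (which include any time-warped copies),
#' validated on the held-out unwarped training repetition, and evaluated on
#' the fixed test repetitions.  The summary row is the mean of the fold
#' overall accuracies.
#'
#' @param split a `split_set` with folds.
#' @param model_cfg a [model_config()].
#' @param train_cfg a [train_config()]; fold i trains with seed
#'   `train_cfg$seed + i` for independent but reproducible runs.
#' @return a `cv_result`: list of per-fold `eval_result`s, the per-fold
#'   fits, and `average_OA`.
#' @export
cross_validate <- function(split, model_cfg, train_cfg = train_config()) {
  stopifnot(inherits(split, "split_set"))
  if (is.null(split$folds)) stopf("split has no folds; call make_folds() first")
  results <- vector("list", length(split$folds))
  fits <- vector("list", length(split$folds))
  for (i in seq_along(split$folds)) {
    f <- split$folds[[i]]
    cfg_i <- train_cfg; cfg_i$seed <- train_cfg$seed + i
    model <- build_model(model_cfg, seed = cfg_i$seed)
    fit <- train(model, split$train[f$train_idx], split$train[f$val_idx],
                 cfg_i)
    results[[i]] <- evaluate(fit, split$test, fold_id = i)
    fits[[i]] <- fit
  }
  structure(list(folds = results, fits = fits,
                 average_OA = mean(vapply(results, `[[`, numeric(1), "OA"))),
            class = "cv_result")
}

#' @export
print.cv_result <- function(x, ...) {
  oas <- vapply(x$folds, `[[`, numeric(1), "OA")
  tab <- matrix(sprintf("%.2f", 100 * c(oas, x$average_OA)), nrow = 1,
                dimnames = list("OA (%)",
                                c(paste("Fold", seq_along(oas)), "Average")))
  print(tab, quote = FALSE)
  invisible(x)
}
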