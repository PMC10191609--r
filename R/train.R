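#' Joint multi-task binary cross-entropy loss
#'
#' Sum over cell types of the (optionally weighted) batch-mean binary
#' cross-entropy between predicted probabilities and 0/1 labels. Predictions
#' are clamped to `[1e-7, 1 - 1e-7]` before the logarithm.
#'
#' @param predictions `n_cells x B` matrix of probabilities in (0, 1).
#' @param labels `n_cells x B` matrix of 0/1 labels.
#' @param weights Per-cell-type loss weights (default uniform 1).
#' @return The scalar joint loss.
#' @export
joint_loss <- function(predictions, labels, weights = NULL) {
  predictions <- rbind(predictions)
  labels <- rbind(labels)
  if (!all(dim(predictions) == dim(labels))) {
    abort("`predictions` and `labels` must have identical shape.")
  }
  if (!all(labels %in% c(0, 1))) abort("labels must be 0/1.")
  if (is.null(weights)) weights <- rep(1, nrow(predictions))
  if (length(weights) != nrow(predictions)) {
    abort("need one loss weight per cell type.")
  }
  if (any(weights < 0)) abort("loss weights must be >= 0.")
  p <- pmin(pmax(predictions, 1e-7), 1 - 1e-7)
  bce <- -rowMeans(labels * log(p) + (1 - labels) * log(1 - p))
  sum(weights * bce)
}

#' Rank-based area under the ROC curve
#'
#' The probability that a random positive outranks a random negative, with
#' ties counted half (midrank formula).
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels.
#' @return auROC in `[0, 1]`, or `NA` if only one class is present.
#' @export
auroc <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Training control parameters
#'
#' @param learning_rate Adam learning rate (default 1e-3).
#' @param batch_size Mini-batch size (default 64).
#' @param max_epochs Maximum epochs (default 20).
#' @param patience Early-stopping patience in epochs on validation
#'   macro-auROC; `Inf` disables early stopping.
#' @param seed Seed controlling initialization, shuffling and dropout.
#' @param loss_weights Per-cell-type loss weights (default uniform).
#' @param verbose Print per-epoch progress.
#' @return A `tfgate_train_control` list.
#' @export
tfgate_train_control <- function(learning_rate = 1e-3, batch_size = 64,
                                 max_epochs = 20, patience = 5, seed = 1,
                                 loss_weights = NULL, verbose = FALSE) {
  stopifnot(learning_rate >= 0, batch_size >= 1, max_epochs >= 1)
  structure(list(learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs), patience = patience,
                 seed = seed, loss_weights = loss_weights, verbose = verbose),
            class = "tfgate_train_control")
}

adam_new <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(theta, grad, st, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  st$m <- beta1 * st$m + (1 - beta1) * grad
  st$v <- beta2 * st$v + (1 - beta2) * grad^2
  mhat <- st$m / (1 - beta1^st$t)
  vhat <- st$v / (1 - beta2^st$t)
  list(theta = theta - lr * mhat / (sqrt(vhat) + eps), state = st)
}

slice_feats <- function(enc, idx) {
  list(kmer = enc$kmer[, , idx, drop = FALSE],
       shape = enc$shape[, , idx, drop = FALSE],
       histone = enc$histone[, , idx, drop = FALSE])
}

# Forward in evaluation mode over arbitrary index sets, batched.
predict_probs <- function(model, enc, idx, batch = 512L) {
  n_cells <- model$config$n_cells
  out <- matrix(0, n_cells, length(idx))
  for (s in split(seq_along(idx), ceiling(seq_along(idx) / batch))) {
    fw <- model_forward(model, slice_feats(enc, idx[s]), train = FALSE)
    out[, s] <- fw$probs
  }
  out
}

#' Fit the gated multi-task model
#'
#' Encodes the dataset into the three feature arrays, then optimizes the
#' joint binary cross-entropy with Adam over mini-batches. When the dataset
#' carries a validation split, macro-average validation auROC is tracked each
#' epoch and the best weights are restored at the end (early stopping with
#' the configured patience). Fully reproducible given `control$seed`.
#'
#' @param dataset A `tfgate_dataset`, ideally already passed through
#'   [split_dataset()]; without a split all samples are used for training.
#' @param config A [tfgate_config()] (default built from the dataset).
#' @param shape_table A `shape_table` for the shape stream (default
#'   [make_shape_table()]).
#' @param control A [tfgate_train_control()].
#' @return A `tfgate_fit` object: best model, per-epoch `history` tibble,
#'   config, shape table and split provenance.
#' @export
tfgate_fit <- function(dataset, config = NULL, shape_table = make_shape_table(),
                       control = tfgate_train_control()) {
  stopifnot(inherits(dataset, "tfgate_dataset"))
  cell_types <- attr(dataset, "cell_types")
  if (is.null(config)) {
    config <- tfgate_config(n_cells = length(cell_types),
                            window_size = attr(dataset, "window_size"))
  }
  if (config$n_cells != length(cell_types)) {
    abort("config$n_cells does not match the dataset's cell types.")
  }
  enc <- encode_dataset(dataset, shape_table, config$kmer_order)
  enc[stream_names()] <- apply_feature_mask(enc[stream_names()], config)
  split <- attr(dataset, "split") %||%
    list(train = seq_len(nrow(dataset)), valid = integer(0),
         test = integer(0))
  labels <- t(enc$labels) # n_cells x N
  weights <- control$loss_weights %||% rep(1, config$n_cells)
  if (length(weights) != config$n_cells) {
    abort("`loss_weights` must have one entry per cell type.")
  }
  model <- init_model(config, seed = control$seed)
  theta <- flatten_params(model$params)
  opt <- adam_new(length(theta))
  history <- list()
  best <- list(metric = -Inf, params = model$params, epoch = 0L)
  wait <- 0L
  with_local_seed(derive_seed(control$seed, "train"), {
    for (epoch in seq_len(control$max_epochs)) {
      ord <- sample(split$train)
      batches <- split(ord, ceiling(seq_along(ord) / control$batch_size))
      epoch_loss <- 0
      for (bi in batches) {
        fw <- model_forward(model, slice_feats(enc, bi), train = TRUE,
                            keep_cache = TRUE)
        lab <- labels[, bi, drop = FALSE]
        loss <- joint_loss(fw$probs, lab, weights)
        if (!is.finite(loss)) abort("training diverged (non-finite loss).")
        epoch_loss <- epoch_loss + loss * length(bi)
        dz <- (fw$probs - lab) * (weights / length(bi))
        grads <- model_backward(model, fw, dz)
        up <- adam_step(theta, flatten_params(grads), opt,
                        control$learning_rate)
        theta <- up$theta
        opt <- up$state
        model$params <- unflatten_params(theta, model$params)
      }
      epoch_loss <- epoch_loss / length(split$train)
      val_auc <- NA_real_
      if (length(split$valid)) {
        pv <- predict_probs(model, enc, split$valid)
        aucs <- vapply(seq_len(config$n_cells), function(k) {
          auroc(pv[k, ], labels[k, split$valid])
        }, numeric(1))
        val_auc <- mean(aucs, na.rm = TRUE)
        if (val_auc > best$metric + 1e-9) {
          best <- list(metric = val_auc, params = model$params, epoch = epoch)
          wait <- 0L
        } else {
          wait <- wait + 1L
        }
      }
      history[[epoch]] <- tibble::tibble(epoch = epoch,
                                         train_loss = epoch_loss,
                                         valid_macro_auroc = val_auc)
      if (control$verbose) {
        inform(sprintf("epoch %d: loss %.4f, valid macro auROC %s", epoch,
                       epoch_loss, ifelse(is.na(val_auc), "-",
                                          sprintf("%.4f", val_auc))))
      }
      if (length(split$valid) && is.finite(control$patience) &&
          wait >= control$patience) break
    }
  })
  if (length(split$valid) && best$epoch > 0L) model$params <- best$params
  structure(list(model = model, config = config,
                 history = dplyr::bind_rows(history),
                 cell_types = cell_types, shape_table = shape_table,
                 control = control, split = split,
                 best_epoch = if (length(split$valid)) best$epoch else
                   nrow(dplyr::bind_rows(history))),
            class = "tfgate_fit")
}

#' @export
print.tfgate_fit <- function(x, ...) {
  cat(sprintf("<tfgate_fit> %d cell type(s): %s\n", length(x$cell_types),
              paste(x$cell_types, collapse = ", ")))
  cat(sprintf("  %d epochs trained, best epoch %d", nrow(x$history),
              x$best_epoch))
  if (any(!is.na(x$history$valid_macro_auroc))) {
    cat(sprintf(" (valid macro auROC %.4f)",
                max(x$history$valid_macro_auroc, na.rm = TRUE)))
  }
  cat("\n")
  invisible(x)
}

#' Predict binding probabilities for a dataset
#'
#' @param object A `tfgate_fit`.
#' @param dataset A `tfgate_dataset` with the same window size.
#' @param indices Optional integer subset of rows to score.
#' @param ... Unused.
#' @return A tibble with `id` and one probability column per cell type.
#' @export
predict.tfgate_fit <- function(object, dataset, indices = NULL, ...) {
  stopifnot(inherits(dataset, "tfgate_dataset"))
  enc <- encode_dataset(dataset, object$shape_table,
                        object$config$kmer_order)
  enc[stream_names()] <- apply_feature_mask(enc[stream_names()],
                                            object$config)
  idx <- indices %||% seq_len(nrow(dataset))
  pr <- predict_probs(object$model, enc, idx)
  out <- tibble::as_tibble(stats::setNames(as.data.frame(t(pr)),
                                           object$cell_types))
  dplyr::bind_cols(tibble::tibble(id = dataset$id[idx]), out)
}
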