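#' Training configuration
#'
#' Defaults follow the study's hyperparameter table: batch size 128,
#' learning rate 0.001 with plateau decay by a factor of 0.5 after
#' `patience` non-improving validation epochs, up to 100 epochs, Adam or
#' RMSprop.
#'
#' @param batch_size minibatch size.
#' @param learning_rate initial learning rate.
#' @param lr_decay_factor multiplicative decay in `(0, 1]` applied on a
#'   validation-loss plateau.
#' @param patience consecutive non-improving epochs (>= 1) before a decay.
#' @param max_epochs maximum number of epochs.
#' @param optimizer `"adam"` or `"rmsprop"`.
#' @param class_weights `"none"` or `"inverse"` (inverse-frequency
#'   per-class loss weights computed on the training split).
#' @param validation_fraction holdout share in `(0, 1)` used when the
#'   fitting function performs its own stratified split.
#' @param seed integer seed; fixes the split, the weight initialization,
#'   the epoch shuffles and dropout, so a rerun is bitwise identical.
#' @param verbose print a line per epoch.
#' @return an object of class `train_config`.
#' @export
train_config <- function(batch_size = 128L, learning_rate = 0.001,
                         lr_decay_factor = 0.5, patience = 2L,
                         max_epochs = 100L,
                         optimizer = c("adam", "rmsprop"),
                         class_weights = c("none", "inverse"),
                         validation_fraction = 0.2,
                         seed = 1L, verbose = FALSE) {
  optimizer <- match.arg(optimizer)
  class_weights <- match.arg(class_weights)
  if (patience < 1L) stop("patience must be >= 1")
  if (lr_decay_factor <= 0 || lr_decay_factor > 1)
    stop("lr_decay_factor must be in (0, 1]")
  if (validation_fraction <= 0 || validation_fraction >= 1)
    stop("validation_fraction must be in (0, 1)")
  structure(list(batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 lr_decay_factor = lr_decay_factor,
                 patience = as.integer(patience),
                 max_epochs = as.integer(max_epochs),
                 optimizer = optimizer, class_weights = class_weights,
                 validation_fraction = validation_fraction,
                 seed = as.integer(seed), verbose = isTRUE(verbose)),
            class = "train_config")
}

# deterministic per-stage substream seeds derived from the master seed,
# so e.g. changing saliency options cannot perturb training randomness
derive_seed <- function(seed, stage) {
  off <- c(init = 1, split = 2, train = 3, synth = 4, xai = 5, data = 6)
  as.integer((abs(as.numeric(seed)) * 7 + off[[stage]]) %% 2147483629)
}

#' Stratified holdout split
#'
#' Partitions sample indices into disjoint, exhaustive train/validation
#' sets, stratified by class: each class contributes
#' `round(fraction * n_class)` validation samples (at least 1, at most
#' `n_class - 1`). Reproducible for a fixed seed.
#'
#' @param labels class labels (factor or integer codes).
#' @param fraction validation share in `(0, 1)`.
#' @param seed integer seed.
#' @return list with integer index vectors `train` and `valid`.
#' @export
holdout_split <- function(labels, fraction = 0.2, seed = 1L) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  lab <- if (is.factor(labels)) as.integer(labels) else as.integer(labels)
  set.seed(derive_seed(seed, "split"))
  valid <- integer(0)
  for (cl in sort(unique(lab))) {
    idx <- which(lab == cl)
    if (length(idx) < 2L)
      stop("class ", cl, " has fewer than 2 samples; cannot stratify")
    nv <- min(max(1L, round(fraction * length(idx))), length(idx) - 1L)
    valid <- c(valid, sample(idx, nv))
  }
  valid <- sort(valid)
  list(train = setdiff(seq_along(lab), valid), valid = valid)
}

#' Fit the multi-branch NGNDG CNN
#'
#' The package's main fitting function: builds the network from `spec`,
#' performs a seeded stratified holdout split, trains with sparse
#' categorical cross-entropy and the configured optimizer, decays the
#' learning rate on validation-loss plateaus, and records per-epoch
#' train/validation loss, accuracy, macro precision/recall and macro AUC.
#'
#' @param x image batch `(N, H, W, C)` with values in `[0, 1]`.
#' @param y class labels: a factor or integer codes `0..C-1`.
#' @param spec a [cnn_spec()]; its `n_classes` must match the labels.
#' @param config a [train_config()].
#' @param class_names optional class names (taken from factor levels when
#'   `y` is a factor).
#' @return an object of class `ngndg_cnn` with components `model` (the
#'   trained network), `spec`, `config`, `history` (one row per epoch),
#'   `classes`, and the index `split`.
#' @seealso [predict.ngndg_cnn()], [evaluate_cnn()], [explain()]
#' @export
ngndg_cnn <- function(x, y, spec = cnn_spec(), config = train_config(),
                      class_names = NULL) {
  stopifnot(inherits(spec, "cnn_spec"), inherits(config, "train_config"))
  x <- check_images(x, spec$input_shape)
  if (is.factor(y) && is.null(class_names)) class_names <- levels(y)
  y <- as_label_index(y, spec$n_classes)
  if (length(y) != dim(x)[1]) stop("x and y disagree on the number of samples")
  if (is.null(class_names)) class_names <- as.character(0:(spec$n_classes - 1L))

  split <- holdout_split(y, config$validation_fraction, config$seed)
  if (length(split$train) == 0L || length(split$valid) == 0L)
    stop("empty train or validation split")

  model <- build_cnn(spec, seed = derive_seed(config$seed, "init"))
  theta <- collect_params(model)
  opt <- switch(config$optimizer,
                adam = adam_init(theta, alpha = config$learning_rate),
                rmsprop = rmsprop_init(theta, alpha = config$learning_rate))
  step_fun <- switch(config$optimizer, adam = adam_step, rmsprop = rmsprop_step)

  w <- rep(1, length(y))
  if (config$class_weights == "inverse") {
    cnt <- tabulate(y[split$train] + 1L, nbins = spec$n_classes)
    cw <- length(split$train) / (spec$n_classes * pmax(cnt, 1L))
    w <- cw[y + 1L]
  }

  xt <- x[split$train, , , , drop = FALSE]; yt <- y[split$train]
  xv <- x[split$valid, , , , drop = FALSE]; yv <- y[split$valid]
  wt <- w[split$train]
  n_train <- length(yt)

  lr <- config$learning_rate
  best <- Inf; wait <- 0L
  hist_rows <- vector("list", config$max_epochs)

  set.seed(derive_seed(config$seed, "train"))
  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample.int(n_train)
    # training metrics are accumulated over the minibatch forward passes
    # (training mode), the usual framework convention
    ep_probs <- matrix(0, n_train, spec$n_classes)
    for (b0 in seq(1L, n_train, by = config$batch_size)) {
      bi <- perm[b0:min(b0 + config$batch_size - 1L, n_train)]
      xb <- to_internal(xt[bi, , , , drop = FALSE])
      fw <- net_forward(model, xb, training = TRUE)
      model <- apply_bn_updates(model, fw$caches)
      nb <- length(bi)
      yb <- matrix(0, nb, spec$n_classes)
      yb[cbind(seq_len(nb), yt[bi] + 1L)] <- 1
      wb <- wt[bi]
      dlogits <- (fw$probs - yb) * (wb / sum(wb))
      bw <- net_backward(model, fw$caches, dlogits)
      grads <- collect_grads(model, bw$pgrads)
      opt$alpha <- lr
      opt <- step_fun(opt, grads)
      model <- set_params(model, opt$theta)
      ep_probs[bi, ] <- fw$probs
    }

    mtr <- list(loss = sparse_ce_loss(ep_probs, yt, weights = wt),
                report = suppressMessages(metrics_report(yt, ep_probs)))
    mvl <- epoch_metrics(model, xv, yv, NULL)
    hist_rows[[epoch]] <- data.frame(
      epoch = epoch, lr = lr,
      train_loss = mtr$loss, train_accuracy = mtr$report$accuracy,
      train_precision = mtr$report$macro_precision,
      train_recall = mtr$report$macro_recall,
      train_auc = mtr$report$macro_auc,
      valid_loss = mvl$loss, valid_accuracy = mvl$report$accuracy,
      valid_precision = mvl$report$macro_precision,
      valid_recall = mvl$report$macro_recall,
      valid_auc = mvl$report$macro_auc)
    if (config$verbose)
      cat(sprintf(
        "epoch %3d  lr %.2e  train loss %.4f acc %.4f | valid loss %.4f acc %.4f\n",
        epoch, lr, mtr$loss, mtr$report$accuracy, mvl$loss,
        mvl$report$accuracy))

    sch <- plateau_update(list(best = best, wait = wait, lr = lr),
                          mvl$loss, config$patience, config$lr_decay_factor)
    best <- sch$best; wait <- sch$wait; lr <- sch$lr
  }

  structure(list(model = model, spec = spec, config = config,
                 history = do.call(rbind, hist_rows),
                 classes = class_names, split = split,
                 call = match.call()),
            class = "ngndg_cnn")
}

# Reduce-on-plateau learning-rate schedule: a decay fires after `patience`
# consecutive epochs without a new best validation loss, then the counter
# resets. After k decay events the rate is exactly lr0 * factor^k.
plateau_update <- function(state, loss, patience, factor) {
  if (loss < state$best) {
    state$best <- loss
    state$wait <- 0L
  } else {
    state$wait <- state$wait + 1L
    if (state$wait >= patience) {
      state$lr <- state$lr * factor
      state$wait <- 0L
    }
  }
  state
}

# eval-mode forward in memory-bounded chunks
predict_probs <- function(model, x, chunk = 256L) {
  n <- dim(x)[1]
  out <- matrix(0, n, model$n_classes)
  for (b0 in seq(1L, n, by = chunk)) {
    bi <- b0:min(b0 + chunk - 1L, n)
    out[bi, ] <- net_forward(model, to_internal(x[bi, , , , drop = FALSE]),
                             training = FALSE)$probs
  }
  out
}

epoch_metrics <- function(model, x, y, w) {
  probs <- predict_probs(model, x)
  list(loss = sparse_ce_loss(probs, y, weights = w),
       report = suppressMessages(metrics_report(y, probs)))
}

#' Evaluate a fitted model on labeled images
#'
#' @param object an `ngndg_cnn` fit (or a raw `ngndg_net`).
#' @param x image batch `(N, H, W, C)`.
#' @param y class labels (factor or integer codes).
#' @return a [metrics_report()].
#' @export
evaluate_cnn <- function(object, x, y) {
  model <- if (inherits(object, "ngndg_cnn")) object$model else object
  stopifnot(inherits(model, "ngndg_net"))
  x <- check_images(x, model$input_shape)
  probs <- predict_probs(model, x)
  cls <- if (inherits(object, "ngndg_cnn")) object$classes else NULL
  metrics_report(y, probs, class_names = cls)
}

#' Predict method for fitted NGNDG CNNs
#'
#' @param object an `ngndg_cnn` fit.
#' @param newdata image batch `(N, H, W, C)` or a single `(H, W, C)` image.
#' @param type `"prob"` for the probability matrix, `"class"` for argmax
#'   labels (a factor over the training classes).
#' @param ... unused.
#' @export
predict.ngndg_cnn <- function(object, newdata,
                              type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- check_images(newdata, object$model$input_shape)
  probs <- predict_probs(object$model, x)
  colnames(probs) <- object$classes
  if (type == "prob") return(probs)
  factor(object$classes[max.col(probs, ties.method = "first")],
         levels = object$classes)
}

#' @export
print.ngndg_cnn <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat("Fitted NGNDG CNN (", x$config$optimizer, ", beta = ",
      x$spec$beta, ")\n", sep = "")
  cat("  ", length(x$split$train), "train /", length(x$split$valid),
      "validation images,", nrow(x$history), "epochs\n")
  cat(sprintf("  final: train acc %.4f loss %.4f | valid acc %.4f loss %.4f\n",
              h$train_accuracy, h$train_loss, h$valid_accuracy, h$valid_loss))
  invisible(x)
}

#' @export
summary.ngndg_cnn <- function(object, ...) {
  print(object)
  cen <- layer_census(object$model)
  cat("\nArchitecture:", nrow(cen), "layers,", sum(cen$n_params),
      "trainable parameters\n")
  print(cen[, c("layer", "kind", "block", "branch", "detail", "activation",
                "output_shape", "n_params")], row.names = FALSE)
  invisible(object)
}

#' Training-history curves
#'
#' Plots train/validation loss and accuracy against the epoch.
#'
#' @param x an `ngndg_cnn` fit.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.ngndg_cnn <- function(x, ...) {
  h <- x$history
  op <- graphics::par(mfrow = c(1, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  graphics::matplot(h$epoch, cbind(h$train_loss, h$valid_loss), type = "l",
                    lty = 1, col = c("black", "red"), xlab = "epoch",
                    ylab = "loss", main = "Loss", ...)
  graphics::legend("topright", c("train", "valid"), lty = 1,
                   col = c("black", "red"), bty = "n")
  graphics::matplot(h$epoch, cbind(h$train_accuracy, h$valid_accuracy),
                    type = "l", lty = 1, col = c("black", "red"),
                    xlab = "epoch", ylab = "accuracy", main = "Accuracy", ...)
  invisible(x)
}
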