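#' Training configuration
#'
#' Defaults follow the reference protocol: Adam with initial learning rate
#' 1e-4, batch size 4, up to 100 epochs, reduce-on-plateau with factor 0.2
#' and patience 10 on the validation loss, early stopping with patience 10,
#' 5-fold cross-validation. (The quoted "weight decay factor of 0.2 and a
#' patience value of 10" is read as a plateau learning-rate schedule --
#' an Adam weight decay of 0.2 would be implausibly large; a true decoupled
#' weight decay can be set through `weight_decay` if wanted.)
#'
#' @param learning_rate Initial Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param max_epochs Maximum training epochs.
#' @param lr_reduce_factor Multiplier applied to the learning rate when the
#'   validation loss has not improved for `lr_patience` epochs.
#' @param lr_patience,early_stop_patience Plateau patiences (epochs).
#' @param n_folds Folds for cross-validation.
#' @param seed Seed controlling initialisation and batch shuffling.
#' @param num_classes Number of categories (4 ILO categories).
#' @param augmentation Logical; apply small random rotation/translation/
#'   brightness jitter to training crops each epoch.
#' @param class_weights Optional per-class loss weights (e.g. inverse
#'   frequency); `NULL` (default) weights all samples equally, since
#'   augmentation-based imbalance handling was found ineffective in the
#'   reference experiments.
#' @param weight_decay Decoupled weight decay coefficient (default 0).
#' @return Object of class `dla_train_config`.
#' @export
train_config <- function(learning_rate = 1e-4, batch_size = 4L, max_epochs = 100L,
                         lr_reduce_factor = 0.2, lr_patience = 10L,
                         early_stop_patience = 10L, n_folds = 5L, seed = 0L,
                         num_classes = 4L, augmentation = FALSE,
                         class_weights = NULL, weight_decay = 0) {
  stopifnot(learning_rate > 0, batch_size >= 1, max_epochs >= 1,
            lr_reduce_factor > 0, lr_reduce_factor < 1,
            lr_patience >= 1, early_stop_patience >= 1,
            n_folds >= 2, num_classes >= 2)
  structure(list(learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 lr_reduce_factor = lr_reduce_factor,
                 lr_patience = as.integer(lr_patience),
                 early_stop_patience = as.integer(early_stop_patience),
                 n_folds = as.integer(n_folds), seed = as.integer(seed),
                 num_classes = as.integer(num_classes),
                 augmentation = isTRUE(augmentation),
                 class_weights = class_weights,
                 weight_decay = weight_decay),
            class = "dla_train_config")
}

#' Build an untrained zone classifier
#'
#' Architecture: three strided 3x3 convolution blocks with rectifier
#' activations (the "tiny" CPU backbone; channels 8, 16, 32 by default),
#' dual attention refinement of the deepest feature map, global average
#' pooling, and a fully connected softmax head. The backbone is fully
#' convolutional, so any input size with at least 8 pixels per side works;
#' all crops within one zone must share dimensions for batching.
#'
#' @param variant Attention variant: `"none"`, `"ca_only"`, `"sa_only"`,
#'   `"sequential"` (default, the best-performing composition) or
#'   `"parallel"`.
#' @param ratio Channel-attention compression ratio (default 16).
#' @param num_classes Output categories.
#' @param channels Channel widths of the three convolution blocks.
#' @param sa_kernel Spatial-attention kernel size (default 7).
#' @param seed Integer seed for weight initialisation.
#' @return Object of class `dla_model` (untrained; see [dla_fit()]).
#' @export
#' @examples
#' m <- dla_build(variant = "sequential", seed = 1)
#' m
dla_build <- function(variant = "sequential", ratio = 16L, num_classes = 4L,
                      channels = c(8L, 16L, 32L), sa_kernel = 7L, seed = 0L) {
  variant <- normalize_variant(variant)
  params <- with_seed(seed, nn_init_params(variant, channels = channels,
                                           num_classes = num_classes,
                                           ratio = ratio, sa_kernel = sa_kernel))
  structure(list(variant = variant, ratio = as.integer(ratio),
                 num_classes = as.integer(num_classes),
                 channels = as.integer(channels), sa_kernel = as.integer(sa_kernel),
                 seed = as.integer(seed), params = params,
                 n_params = sum(vapply(params, length, 0L)),
                 trained = FALSE, history = NULL, best_epoch = NA_integer_,
                 config = NULL),
            class = "dla_model")
}

#' Stratified image-level cross-validation folds
#'
#' Assigns every image to exactly one fold so that per-class counts differ
#' by at most one between folds. Assignment is by image: all six zone
#' samples of an image inherit its fold, which prevents leakage of an
#' image between a zone model's training and validation splits.
#'
#' @param y Image-level class labels (one per image), or a manifest data
#'   frame with an `image_label` column.
#' @param n_folds Number of folds.
#' @param seed Shuffling seed.
#' @return Integer vector of fold indices (1..n_folds), one per image.
#' @export
stratified_folds <- function(y, n_folds = 5L, seed = 0L) {
  if (is.data.frame(y)) y <- y$image_label
  fold <- integer(length(y))
  with_seed(seed, {
    for (cl in sort(unique(y))) {
      idx <- which(y == cl)
      if (length(idx) < n_folds)
        stop(sprintf("stratification error: class %s has %d image(s), fewer than %d folds",
                     cl, length(idx), n_folds))
      idx <- idx[sample.int(length(idx))]
      fold[idx] <- rep_len(seq_len(n_folds), length(idx))
    }
  })
  fold
}

as_class_index <- function(y, num_classes) {
  if (is.factor(y)) y <- as.integer(y) - 1L
  y <- as.integer(y)
  if (any(y < 0 | y >= num_classes))
    stop_param("labels must lie in 0..%d", num_classes - 1)
  y + 1L
}

#' Fit a zone classifier
#'
#' Minimises the categorical cross-entropy with Adam, multiplying the
#' learning rate by `lr_reduce_factor` whenever the validation loss fails
#' to improve for `lr_patience` epochs, and stopping early after
#' `early_stop_patience` non-improving epochs. The returned model carries
#' the weights of the best validation epoch and a per-epoch history.
#'
#' @param x Training images: an `H x W x N` array or a list of equally
#'   sized matrices.
#' @param y Training categories, integers `0..num_classes-1` (or a factor).
#' @param x_val,y_val Validation split; when omitted the training data are
#'   reused for validation (useful for overfit sanity checks only).
#' @param model A [dla_build()] model, or `NULL` to build one from
#'   `variant`, `ratio` and `config$seed`.
#' @param variant,ratio Passed to [dla_build()] when `model` is `NULL`.
#' @param config A [train_config()].
#' @param verbose Print one line per epoch.
#' @return The fitted `dla_model`, with `history` (a data frame of epoch,
#'   learning rate, training loss, validation loss and accuracy),
#'   `best_epoch` and the best-epoch weights.
#' @seealso [predict.dla_model()], [plot.dla_model()]
#' @export
dla_fit <- function(x, y, x_val = NULL, y_val = NULL, model = NULL,
                    variant = "sequential", ratio = 16L,
                    config = train_config(), verbose = FALSE) {
  stopifnot(inherits(config, "dla_train_config"))
  if (is.null(model))
    model <- dla_build(variant = variant, ratio = ratio,
                       num_classes = config$num_classes, seed = config$seed)
  xs <- nn_stack_input(x)
  yi <- as_class_index(y, model$num_classes)
  n <- dim(xs)[4]
  if (n == 0 || length(yi) != n) stop("data error: empty or mismatched training split")
  if (is.null(x_val)) { x_val <- x; y_val <- y }
  xv <- nn_stack_input(x_val)
  yv <- as_class_index(y_val, model$num_classes)
  if (dim(xv)[4] == 0) stop("data error: empty validation split")

  params <- model$params
  state <- adam_init(params)
  lr <- config$learning_rate
  best <- list(loss = Inf, params = params, epoch = 0L)
  wait_lr <- 0L; wait_stop <- 0L
  hist <- vector("list", config$max_epochs)

  eval_val <- function(params) {
    nv <- dim(xv)[4]; losses <- 0; correct <- 0
    for (b in split(seq_len(nv), ceiling(seq_len(nv) / 64))) {
      fw <- nn_forward(params, xs_slice(xv, b), model$variant)
      py <- fw$probs[cbind(yv[b], seq_along(b))]
      losses <- losses - sum(log(pmax(py, 1e-12)))
      correct <- correct + sum(max.col(t(fw$probs), "first") == yv[b])
    }
    list(loss = losses / nv, acc = correct / nv)
  }

  for (epoch in seq_len(config$max_epochs)) {
    ord <- with_seed(derive_stream_seed(config$seed, epoch), sample.int(n))
    tr_loss <- 0
    for (b in split(ord, ceiling(seq_along(ord) / config$batch_size))) {
      xb <- xs_slice(xs, b)
      if (config$augmentation) {
        for (j in seq_along(b))
          xb[, , 1, j] <- augment_image(xb[, , 1, j],
                                        seed = derive_stream_seed(config$seed, epoch * 100003 + b[j]))
      }
      out <- nn_loss_grad(params, xb, yi[b], model$variant, config$class_weights)
      if (!is.finite(out$loss))
        stop(sprintf("divergence error: non-finite training loss at epoch %d", epoch))
      if (config$weight_decay > 0)
        for (nm in grep("_w", names(params), value = TRUE))
          out$grads[[nm]] <- out$grads[[nm]] + config$weight_decay * params[[nm]]
      upd <- adam_step(params, out$grads, state, lr)
      params <- upd$params; state <- upd$state
      tr_loss <- tr_loss + out$loss * length(b)
    }
    tr_loss <- tr_loss / n
    vl <- eval_val(params)
    hist[[epoch]] <- data.frame(epoch = epoch, lr = lr, train_loss = tr_loss,
                                val_loss = vl$loss, val_acc = vl$acc)
    if (verbose)
      message(sprintf("epoch %3d  lr %.2g  train %.4f  val %.4f  acc %.3f",
                      epoch, lr, tr_loss, vl$loss, vl$acc))
    if (vl$loss < best$loss - 1e-8) {
      best <- list(loss = vl$loss, params = params, epoch = epoch)
      wait_lr <- 0L; wait_stop <- 0L
    } else {
      wait_lr <- wait_lr + 1L; wait_stop <- wait_stop + 1L
      if (wait_lr >= config$lr_patience) {
        lr <- lr * config$lr_reduce_factor
        wait_lr <- 0L
      }
      if (wait_stop >= config$early_stop_patience) break
    }
  }
  model$params <- best$params
  model$best_epoch <- best$epoch
  model$history <- do.call(rbind, hist[!vapply(hist, is.null, TRUE)])
  model$trained <- TRUE
  model$config <- config
  model
}

xs_slice <- function(xs, idx) xs[, , , idx, drop = FALSE]

#' Predict zone categories
#'
#' @param object A fitted [dla_fit()] model.
#' @param newdata Images in the formats accepted by [dla_fit()].
#' @param type `"response"` returns a data frame of class probabilities
#'   (`p0..p{K-1}`) plus the `predicted` category; `"class"` returns just
#'   the predicted categories. Ties in the probabilities resolve to the
#'   lower category.
#' @param ... Unused.
#' @return Data frame or integer vector; categories are 0-based.
#' @export
predict.dla_model <- function(object, newdata, type = c("response", "class"), ...) {
  type <- match.arg(type)
  xs <- nn_stack_input(newdata)
  n <- dim(xs)[4]
  probs <- matrix(0, n, object$num_classes)
  for (b in split(seq_len(n), ceiling(seq_len(n) / 64)))
    probs[b, ] <- t(nn_forward(object$params, xs_slice(xs, b), object$variant)$probs)
  pred <- max.col(probs, ties.method = "first") - 1L
  if (type == "class") return(pred)
  out <- as.data.frame(probs)
  names(out) <- paste0("p", seq_len(object$num_classes) - 1)
  out$predicted <- pred
  out
}

#' @export
print.dla_model <- function(x, ...) {
  cat(sprintf("Zone classifier (dual-attention CNN)\n"))
  cat(sprintf("  backbone channels: %s | attention: %s (ratio %d) | classes: %d\n",
              paste(x$channels, collapse = "-"), x$variant, x$ratio, x$num_classes))
  cat(sprintf("  parameters: %d | %s\n", x$n_params,
              if (x$trained) sprintf("trained, best epoch %d (val loss %.4f, val acc %.3f)",
                                     x$best_epoch,
                                     x$history$val_loss[x$best_epoch],
                                     x$history$val_acc[x$best_epoch])
              else "untrained"))
  invisible(x)
}

#' @export
summary.dla_model <- function(object, ...) {
  print(object)
  cat("\nParameter blocks:\n")
  for (nm in names(object$params))
    cat(sprintf("  %-8s %s (%d)\n", nm,
                paste(dim(object$params[[nm]]) %||% length(object$params[[nm]]),
                      collapse = "x"),
                length(object$params[[nm]])))
  if (!is.null(object$history)) {
    cat("\nTraining history (last epochs):\n")
    print(utils::tail(object$history, 5), row.names = FALSE)
  }
  invisible(object)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
coef.dla_model <- function(object, ...) object$params

#' Plot training history
#'
#' Training and validation loss per epoch (left axis) and validation
#' accuracy (right axis), with the best epoch marked.
#'
#' @param x Fitted `dla_model`.
#' @param ... Passed to [plot()].
#' @export
plot.dla_model <- function(x, ...) {
  h <- x$history
  if (is.null(h)) stop("model has no training history")
  plot(h$epoch, h$train_loss, type = "l", col = "grey40",
       xlab = "epoch", ylab = "cross-entropy loss",
       ylim = range(c(h$train_loss, h$val_loss)), ...)
  lines(h$epoch, h$val_loss, col = "firebrick")
  abline(v = x$best_epoch, lty = 3)
  par(new = TRUE)
  plot(h$epoch, h$val_acc, type = "l", col = "steelblue", axes = FALSE,
       xlab = "", ylab = "", ylim = c(0, 1))
  axis(4); mtext("validation accuracy", side = 4, line = 2)
  legend("bottomleft", legend = c("train loss", "val loss", "val acc"),
         col = c("grey40", "firebrick", "steelblue"), lty = 1, bty = "n")
  invisible(x)
}
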