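#' Decoder configuration
#'
#' Defaults reproduce the architecture and training settings selected by the
#' hyperparameter search for the response-speed decoding task: four
#' convolution blocks of 52/104/156/208 filters with 5x5 kernels, each
#' followed by an inception-style reduction; fully connected layers of 713
#' and 1019 units with dropout 0.47 after each; ELU activations throughout;
#' a 3-unit softmax head; Adagrad at learning rate 0.006; 165 epochs with a
#' 25 percent validation split, best-validation-loss checkpointing and
#' learning-rate reduction on plateau.
#'
#' @param conv_filters Filter counts, one per convolution block.
#' @param kernel Convolution kernel size.
#' @param fc_units Fully connected layer widths.
#' @param dropout Dropout rate after each FC layer, in `[0, 1)`.
#' @param activation Activation name (only `"elu"` is implemented).
#' @param optimizer One of `"adagrad"`, `"adam"`, `"sgd"`.
#' @param learning_rate Positive learning rate.
#' @param epochs Training epochs.
#' @param val_fraction Fraction of the training data held out for
#'   validation, in (0, 1).
#' @param batch_size Minibatch size.
#' @param n_classes Number of output classes.
#' @param plateau_patience,plateau_factor,min_lr Learning-rate schedule: the
#'   rate is multiplied by `plateau_factor` after `plateau_patience` epochs
#'   without validation-loss improvement, floored at `min_lr`.
#' @param seed Integer seed for initialization, shuffling and dropout.
#' @return An object of class `decoder_config`.
#' @export
decoder_config <- function(conv_filters = c(52, 104, 156, 208), kernel = 5,
                           fc_units = c(713, 1019), dropout = 0.47,
                           activation = "elu", optimizer = "adagrad",
                           learning_rate = 0.006, epochs = 165,
                           val_fraction = 0.25, batch_size = 64,
                           n_classes = 3, plateau_patience = 5,
                           plateau_factor = 0.5, min_lr = 1e-5, seed = 1L) {
  stopifnot(dropout >= 0, dropout < 1, val_fraction > 0, val_fraction < 1,
            learning_rate > 0, epochs >= 0, length(conv_filters) >= 1)
  if (tolower(activation) != "elu") stop("only the ELU activation is implemented")
  structure(
    list(conv_filters = as.integer(conv_filters), kernel = as.integer(kernel),
         n_blocks = length(conv_filters), fc_units = as.integer(fc_units),
         dropout = dropout, activation = "elu", optimizer = tolower(optimizer),
         learning_rate = learning_rate, epochs = as.integer(epochs),
         val_fraction = val_fraction, batch_size = as.integer(batch_size),
         n_classes = as.integer(n_classes), plateau_patience = plateau_patience,
         plateau_factor = plateau_factor, min_lr = min_lr, seed = as.integer(seed)),
    class = "decoder_config"
  )
}

#' Build an (untrained) convolutional decoder
#'
#' Architecture: `[convolution (ELU) -> inception reduction] x n_blocks`,
#' flatten, FC stack with dropout after each FC layer, linear class head
#' (softmax applied at prediction). Each reduction halves the spatial size
#' (ceiling division); building fails naming the offending block if a
#' reduction would underflow.
#'
#' @param config A [decoder_config()].
#' @param input_shape `c(H, W, C)` of the input images.
#' @return An object of class `trained_decoder` with freshly initialized
#'   weights, empty history and `label_order = NULL` until trained.
#' @export
build_decoder <- function(config, input_shape) {
  stopifnot(inherits(config, "decoder_config"), length(input_shape) == 3)
  layers <- list()
  for (b in seq_len(config$n_blocks)) {
    layers <- c(layers, list(nn_conv(config$conv_filters[b], config$kernel, 1L),
                             nn_elu(),
                             nn_inception_reduce(config$conv_filters[b])))
  }
  layers <- c(layers, list(nn_flatten()))
  for (u in config$fc_units) {
    layers <- c(layers, list(nn_dense(u), nn_elu(), nn_dropout(config$dropout)))
  }
  layers <- c(layers, list(nn_dense(config$n_classes)))
  init <- with_local_seed(config$seed, nn_init(layers, as.integer(input_shape)))
  structure(
    list(layers = init$layers, config = config,
         input_shape = as.integer(input_shape),
         history = NULL, label_order = NULL),
    class = "trained_decoder"
  )
}

#' @export
print.trained_decoder <- function(x, ...) {
  cat(sprintf("<trained_decoder> input %s, %d blocks (%s), FC %s, %s params\n",
              paste(x$input_shape, collapse = "x"), x$config$n_blocks,
              paste(x$config$conv_filters, collapse = "/"),
              paste(x$config$fc_units, collapse = "/"),
              format(n_params(x), big.mark = ",")))
  if (!is.null(x$history)) {
    cat(sprintf("  trained %d epochs, best val loss %.4f (epoch %d)\n",
                nrow(x$history), min(x$history$val_loss),
                which.min(x$history$val_loss)))
  }
  invisible(x)
}

#' Trainable parameter count
#' @param decoder A `trained_decoder`.
#' @return Total number of weights and biases.
#' @export
n_params <- function(decoder) nn_n_params(decoder$layers)

# images: (N, H, W, C) -> engine layout (H, W, C, N)
to_engine <- function(images) aperm(images, c(2, 3, 4, 1))

#' Train a decoder
#'
#' Categorical cross-entropy on a softmax head, minibatch updates with the
#' configured optimizer, a stratified validation split, checkpointing of the
#' best-validation-loss weights (restored on return), and learning-rate
#' halving on validation plateau. With `epochs = 0` the initialized weights
#' are returned unchanged. Deterministic given `config$seed`.
#'
#' @param decoder A [build_decoder()] result.
#' @param images Array `(N, H, W, C)` of input images in `[0, 1]`.
#' @param labels Factor (or coercible) of class labels, >= 2 classes present.
#' @param config Optional [decoder_config()] override; defaults to the
#'   decoder's own config.
#' @return The trained `trained_decoder` with a `history` data frame
#'   (epoch, lr, train_loss, train_acc, val_loss, val_acc).
#' @export
train_decoder <- function(decoder, images, labels, config = decoder$config) {
  stopifnot(inherits(decoder, "trained_decoder"))
  labels <- factor(labels)
  if (nlevels(droplevels(labels)) < 2) stop("need at least 2 classes to train")
  N <- dim(images)[1]
  stopifnot(length(labels) == N)
  decoder$label_order <- levels(labels)
  if (config$epochs == 0) {
    decoder$history <- data.frame()
    return(decoder)
  }
  y_idx <- as.integer(labels)
  K <- nlevels(labels)

  with_local_seed(config$seed, {
    # stratified validation split
    val <- unlist(lapply(split(seq_len(N), labels), function(ix) {
      nv <- max(1L, round(length(ix) * config$val_fraction))
      sample(ix, nv)
    }), use.names = FALSE)
    tr <- setdiff(seq_len(N), val)

    Xtr <- to_engine(images[tr, , , , drop = FALSE]); ytr <- y_idx[tr]
    Xva <- to_engine(images[val, , , , drop = FALSE]); yva <- y_idx[val]

    refs <- nn_collect_params(decoder$layers)
    opt <- make_optimizer(config$optimizer, config$learning_rate)
    best <- list(loss = Inf, layers = decoder$layers, epoch = 0L)
    wait <- 0L
    hist <- vector("list", config$epochs)

    for (ep in seq_len(config$epochs)) {
      ord <- sample(length(tr))
      ep_loss <- 0; ep_correct <- 0
      for (b0 in seq(1, length(tr), by = config$batch_size)) {
        bidx <- ord[b0:min(b0 + config$batch_size - 1, length(tr))]
        xb <- Xtr[, , , bidx, drop = FALSE]
        yb <- ytr[bidx]
        fw <- nn_forward(decoder$layers, xb, training = TRUE)
        probs <- softmax(fw$out)
        nb <- length(bidx)
        onehot <- matrix(0, nb, K); onehot[cbind(seq_len(nb), yb)] <- 1
        ep_loss <- ep_loss - sum(log(pmax(probs[cbind(seq_len(nb), yb)], 1e-12)))
        ep_correct <- ep_correct + sum(max.col(probs) == yb)
        dy <- (probs - onehot) / nb
        bw <- nn_backward(decoder$layers, fw$caches, dy)
        for (ri in seq_along(refs)) {
          w <- nn_get_param(decoder$layers, refs[[ri]])
          g <- nn_get_grad(bw$grads, refs[[ri]])
          decoder$layers <- nn_set_param(decoder$layers, refs[[ri]],
                                         opt$step(ri, w, g))
        }
      }
      va <- nn_forward(decoder$layers, Xva, training = FALSE)
      vp <- softmax(va$out)
      val_loss <- -mean(log(pmax(vp[cbind(seq_along(yva), yva)], 1e-12)))
      val_acc <- mean(max.col(vp) == yva)
      hist[[ep]] <- data.frame(epoch = ep, lr = opt$state$lr,
                               train_loss = ep_loss / length(tr),
                               train_acc = ep_correct / length(tr),
                               val_loss = val_loss, val_acc = val_acc)
      if (val_loss < best$loss - 1e-9) {
        best <- list(loss = val_loss, layers = decoder$layers, epoch = ep)
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= config$plateau_patience) {
          opt$state$lr <- max(config$min_lr, opt$state$lr * config$plateau_factor)
          wait <- 0L
        }
      }
    }
    decoder$layers <- best$layers
    decoder$history <- do.call(rbind, hist)
    decoder$best_epoch <- best$epoch
  })
  decoder
}

#' Class probabilities for new images
#'
#' @param object A trained `trained_decoder`.
#' @param images Array `(N, H, W, C)`.
#' @param ... Unused.
#' @return Matrix `N x n_classes` of softmax probabilities, columns named by
#'   `label_order` when available.
#' @export
predict.trained_decoder <- function(object, images, ...) {
  fw <- nn_forward(object$layers, to_engine(images), training = FALSE)
  p <- softmax(fw$out)
  if (!is.null(object$label_order)) colnames(p) <- object$label_order
  p
}

#' Classification metrics
#'
#' Per-class precision, recall and F1 with macro and weighted averages, the
#' row-normalized confusion matrix, per-class average precision from a
#' score-threshold sweep, and the mean softmax score assigned to the correct
#' class.
#'
#' @param decoder A trained `trained_decoder`.
#' @param images Array `(N, H, W, C)`.
#' @param labels True labels.
#' @return A list with `per_class`, `macro`, `weighted`, `accuracy`,
#'   `confusion` (row-normalized), `average_precision`,
#'   `mean_correct_score`.
#' @export
evaluate_decoder <- function(decoder, images, labels) {
  probs <- predict(decoder, images)
  labels <- factor(labels, levels = decoder$label_order %||% levels(factor(labels)))
  if (length(labels) != nrow(probs)) stop("label/prediction length mismatch")
  pred <- factor(decoder$label_order[max.col(probs)], levels = levels(labels))
  classification_metrics(labels, pred, probs)
}

# metrics from labels/predictions/scores; split out so toy contingency
# tables can be scored without a decoder
classification_metrics <- function(labels, pred, probs = NULL) {
  lv <- levels(labels)
  cm <- table(truth = labels, pred = factor(pred, levels = lv))
  tp <- diag(cm)
  prec <- ifelse(colSums(cm) > 0, tp / colSums(cm), 0)
  rec <- ifelse(rowSums(cm) > 0, tp / rowSums(cm), 0)
  f1 <- ifelse(prec + rec > 0, 2 * prec * rec / (prec + rec), 0)
  support <- rowSums(cm)
  per_class <- data.frame(class = lv, precision = as.numeric(prec),
                          recall = as.numeric(rec), f1 = as.numeric(f1),
                          support = as.numeric(support))
  macro <- c(precision = mean(prec), recall = mean(rec), f1 = mean(f1))
  wts <- support / sum(support)
  weighted <- c(precision = sum(prec * wts), recall = sum(rec * wts),
                f1 = sum(f1 * wts))
  out <- list(per_class = per_class, macro = macro, weighted = weighted,
              accuracy = sum(tp) / sum(cm),
              confusion = sweep(unclass(cm), 1, pmax(rowSums(cm), 1), `/`))
  if (!is.null(probs)) {
    ap <- vapply(seq_along(lv), function(k) {
      average_precision(labels == lv[k], probs[, k])
    }, numeric(1))
    names(ap) <- lv
    out$average_precision <- ap
    out$mean_correct_score <- mean(probs[cbind(seq_along(labels), as.integer(labels))])
  }
  out
}

# area under the precision-recall step curve (threshold sweep)
average_precision <- function(truth, score) {
  ord <- order(score, decreasing = TRUE)
  truth <- as.logical(truth)[ord]
  if (!any(truth)) return(NA_real_)
  tp <- cumsum(truth)
  prec <- tp / seq_along(truth)
  rec <- tp / sum(truth)
  sum(diff(c(0, rec)) * prec)
}
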