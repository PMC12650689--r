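#' Build an untrained 1-D convolutional classifier
#'
#' Three fixed architecture variants over a length-`input_dim`, 1-channel
#' input sequence:
#'
#' * **variant 1**: conv1d(64 filters, kernel 3, ReLU) -> max-pool(width 2)
#'   -> dropout 0.5 -> flatten -> output layer;
#' * **variant 2**: conv1d(64, 3, ReLU) -> dropout 0.25 -> max-pool(2)
#'   -> flatten -> dense(128, ReLU) -> dropout 0.25 -> output layer;
#' * **variant 3**: variant 2 with both dropout rates at 0.5.
#'
#' The output layer has one logistic unit when `n_classes = 2` and
#' `n_classes` softmax units otherwise. Weights are initialized with
#' Glorot-uniform draws from the R RNG.
#'
#' @param variant 1, 2 or 3.
#' @param n_classes 2, 4 or 7.
#' @param input_dim feature-vector length (default 310).
#' @param seed seed for weight initialization.
#' @return an object of class `eeg_cnn` (unfitted).
#' @export
build_cnn <- function(variant = 1, n_classes, input_dim = 310, seed = 1) {
  if (!variant %in% 1:3) stop("unknown model variant: ", variant, call. = FALSE)
  stopifnot(n_classes >= 2)
  if (input_dim < 6) stop("input_dim must be at least 6", call. = FALSE)
  out_dim <- if (n_classes == 2) 1L else as.integer(n_classes)
  L <- input_dim - 2L
  Lp <- L %/% 2L
  flat <- Lp * 64L
  glorot <- function(nr, nc, fan_in, fan_out) {
    lim <- sqrt(6 / (fan_in + fan_out))
    matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
  }
  w <- with_seed_(derive_seed(seed, "cnn-init"), {
    w <- list(W1 = glorot(3, 64, 3, 64), b1 = rep(0, 64))
    if (variant == 1) {
      w$Wout <- glorot(flat, out_dim, flat, out_dim)
    } else {
      w$Wd <- glorot(flat, 128, flat, 128)
      w$bd <- rep(0, 128)
      w$Wout <- glorot(128, out_dim, 128, out_dim)
    }
    w$bout <- rep(0, out_dim)
    w
  })
  drop_rate <- c(0.5, 0.25, 0.5)[variant]
  head_act <- if (out_dim == 1L) "sigmoid" else "softmax"
  layers <- if (variant == 1) {
    list(list(type = "conv1d", filters = 64, kernel = 3, activation = "relu"),
         list(type = "maxpool1d", width = 2),
         list(type = "dropout", rate = 0.5),
         list(type = "flatten", units = flat),
         list(type = "dense", units = out_dim, activation = head_act))
  } else {
    list(list(type = "conv1d", filters = 64, kernel = 3, activation = "relu"),
         list(type = "dropout", rate = drop_rate),
         list(type = "maxpool1d", width = 2),
         list(type = "flatten", units = flat),
         list(type = "dense", units = 128, activation = "relu"),
         list(type = "dropout", rate = drop_rate),
         list(type = "dense", units = out_dim, activation = head_act))
  }
  structure(list(variant = as.integer(variant), n_classes = as.integer(n_classes),
                 input_dim = as.integer(input_dim), out_dim = out_dim,
                 layers = layers, weights = w, fitted = FALSE,
                 classes = NULL, positive = NULL, center = NULL, scale = NULL,
                 loss_history = NULL),
            class = "eeg_cnn")
}

#' Train a 1-D convolutional classifier
#'
#' Trains with Adam on (binary or categorical) cross-entropy, matching the
#' head activation. Features are standardized per feature with statistics of
#' the supplied (training) data; the statistics are stored on the model and
#' re-applied at prediction time. All randomness (shuffling, dropout) is
#' reproducible given `seed`.
#'
#' @param model an `eeg_cnn` from [build_cnn()].
#' @param x numeric feature matrix (rows = trials).
#' @param y factor (or vector coercible to factor) of class labels; its
#'   levels define the class order. For two classes the positive class is
#'   `positive` (default: the first level).
#' @param epochs training epochs (default 50).
#' @param learning_rate Adam learning rate (default 1e-4).
#' @param batch_size mini-batch size (default 32).
#' @param seed RNG seed.
#' @param positive positive-class label for the binary head.
#' @param standardize z-score features with training statistics
#'   (default `TRUE`).
#' @param dropout apply the architecture's dropout layers during training
#'   (default `TRUE`; `FALSE` trains deterministically without regularization,
#'   useful for debugging and order-equivariance checks).
#' @return the fitted `eeg_cnn`, with `loss_history` of length `epochs`.
#' @export
cnn_train <- function(model, x, y, epochs = 50, learning_rate = 1e-4,
                      batch_size = 32, seed = 1, positive = NULL,
                      standardize = TRUE, dropout = TRUE) {
  stopifnot(inherits(model, "eeg_cnn"), is.matrix(x))
  y <- as.factor(y)
  if (nrow(x) != length(y)) stop("rows of x must match length of y",
                                 call. = FALSE)
  if (ncol(x) != model$input_dim) {
    stop("x has ", ncol(x), " features; model expects ", model$input_dim,
         call. = FALSE)
  }
  classes <- levels(y)
  if (length(classes) != model$n_classes) {
    if (length(unique(y)) < model$n_classes) {
      warning("only ", length(unique(y)), " of ", model$n_classes,
              " classes present in y (can happen after aggressive cleaning)")
    }
    if (length(classes) > model$n_classes) {
      stop("y has more levels than the model's n_classes", call. = FALSE)
    }
  }
  if (model$out_dim == 1L) {
    if (is.null(positive)) positive <- classes[1]
    if (!positive %in% classes) stop("positive class not among levels of y",
                                     call. = FALSE)
    yint <- as.integer(y == positive)
    model$positive <- positive
  } else {
    if (any(tabulate(y, nbins = length(classes)) == 0L)) {
      warning("class(es) absent from y: ",
              paste(classes[tabulate(y, nbins = length(classes)) == 0L],
                    collapse = ", "),
              " (can happen after aggressive cleaning)")
    }
    yint <- as.integer(y) - 1L
  }
  if (standardize) {
    ctr <- colMeans(x)
    scl <- apply(x, 2, stats::sd)
    scl[!is.finite(scl) | scl < 1e-8] <- 1
    x <- sweep(sweep(x, 2, ctr), 2, scl, "/")
    model$center <- ctr
    model$scale <- scl
  }
  rates <- list(c(0, 0.5, 0), c(0.25, 0, 0.25),
                c(0.5, 0, 0.5))[[model$variant]]
  if (!isTRUE(dropout)) rates <- c(0, 0, 0)
  fit <- with_seed_(derive_seed(seed, "cnn-train"),
    cnn_train_cpp(x, yint, model$out_dim, model$variant, as.integer(epochs),
                  learning_rate, as.integer(batch_size), model$weights,
                  rates[1], rates[2], rates[3], 0.9, 0.999, 1e-8))
  model$weights <- fit$weights
  model$loss_history <- as.numeric(fit$loss)
  model$classes <- classes
  model$fitted <- TRUE
  model
}

#' Fit a 1-D CNN classifier in one call
#'
#' Convenience wrapper: [build_cnn()] then [cnn_train()].
#'
#' @inheritParams cnn_train
#' @inheritParams build_cnn
#' @param ... passed to [cnn_train()].
#' @return a fitted `eeg_cnn`.
#' @export
cnn_fit <- function(x, y, variant = 1, epochs = 50, learning_rate = 1e-4,
                    batch_size = 32, seed = 1, positive = NULL, ...) {
  y <- as.factor(y)
  model <- build_cnn(variant, n_classes = nlevels(y), input_dim = ncol(x),
                     seed = seed)
  cnn_train(model, x, y, epochs = epochs, learning_rate = learning_rate,
            batch_size = batch_size, seed = seed, positive = positive, ...)
}

#' Predict from a fitted CNN
#'
#' Binary head: probability at or above 0.5 predicts the positive class (ties
#' go to the positive class). Multi-class head: arg-max over softmax
#' probabilities.
#'
#' @param object a fitted `eeg_cnn`.
#' @param newdata numeric feature matrix.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... unused.
#' @return factor of predicted classes, or a probability matrix with one
#'   column per class.
#' @export
predict.eeg_cnn <- function(object, newdata, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  if (!object$fitted) stop("model is not fitted", call. = FALSE)
  stopifnot(is.matrix(newdata))
  if (ncol(newdata) != object$input_dim) {
    stop("newdata has ", ncol(newdata), " features; model expects ",
         object$input_dim, call. = FALSE)
  }
  x <- newdata
  if (!is.null(object$center)) {
    x <- sweep(sweep(x, 2, object$center), 2, object$scale, "/")
  }
  pr <- cnn_forward_cpp(x, object$weights, object$variant, object$out_dim)
  if (object$out_dim == 1L) {
    neg <- setdiff(object$classes, object$positive)
    probs <- cbind(pr[, 1], 1 - pr[, 1])
    colnames(probs) <- c(object$positive, neg)
    probs <- probs[, object$classes, drop = FALSE]
    if (type == "prob") return(probs)
    factor(ifelse(pr[, 1] >= 0.5, object$positive, neg),
           levels = object$classes)
  } else {
    colnames(pr) <- object$classes
    if (type == "prob") return(pr)
    factor(object$classes[max.col(pr, ties.method = "first")],
           levels = object$classes)
  }
}

#' Number of trainable parameters
#'
#' @param model an `eeg_cnn`.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$weights, length, integer(1)))
}

#' @export
print.eeg_cnn <- function(x, ...) {
  cat("eeg_cnn variant", x$variant, "-", x$n_classes, "classes, input",
      x$input_dim, "\n")
  for (ly in x$layers) {
    cat("  ", ly$type,
        paste(vapply(setdiff(names(ly), "type"),
                     function(nm) paste0(nm, "=", ly[[nm]]), character(1)),
              collapse = " "), "\n")
  }
  cat("  parameters:", n_parameters(x),
      if (x$fitted) paste0("| fitted, final loss ",
                           signif(utils::tail(x$loss_history, 1), 4))
      else "| not fitted", "\n")
  invisible(x)
}

#' @export
summary.eeg_cnn <- function(object, ...) {
  print(object)
  if (object$fitted) {
    cat("loss history (first/last 5):",
        paste(signif(utils::head(object$loss_history, 5), 4), collapse = " "),
        "...",
        paste(signif(utils::tail(object$loss_history, 5), 4), collapse = " "),
        "\n")
  }
  invisible(object)
}
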