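#' Train an LSTM risk classifier
#'
#' Mini-batch training of the [lstm_params()] model by backpropagation
#' through time under any [make_optimizer()] kind. Records are encoded one
#' feature per timestep (importance order) by default; gradients are
#' averaged over each mini-batch; shuffling, initialisation and the
#' optimizer trajectory are all driven by `seed`, so a fixed
#' (data, seed) pair reproduces the trajectory bit for bit.
#'
#' @param x Numeric matrix, one row per record, columns = model features
#'   in the desired (importance) order.
#' @param y Binary label vector.
#' @param hidden_dim Hidden state size (default 16).
#' @param variant `"standard"` or `"softsign"` candidate activation.
#' @param optimizer Optimizer name (see [make_optimizer()]) or a
#'   ready-made `cp_optimizer`.
#' @param opt_cfg Optional config overrides for the optimizer.
#' @param epochs Training epochs (ignored when `max_steps` is given).
#' @param max_steps Optional cap on total optimizer steps.
#' @param batch_size Mini-batch size (default 64).
#' @param seed Integer seed for init + shuffling.
#' @param mode Sequence encoding, `"per_feature_step"` or `"single_step"`.
#' @param forget_bias Initial forget-gate bias (default 0).
#' @param checkpoint_steps Optional step counts at which to evaluate on
#'   `eval_x`/`eval_y` (accuracy and loss).
#' @param eval_x,eval_y Optional held-out matrix/labels for checkpoints.
#' @return A `cardio_lstm` model: parameters, feature order, training
#'   history (`step`, `loss`) and any checkpoint evaluations.
#' @export
train_lstm <- function(x, y, hidden_dim = 16, variant = "softsign",
                       optimizer = "r-lookahead", opt_cfg = NULL,
                       epochs = 50, max_steps = NULL, batch_size = 64,
                       seed = 1L, mode = "per_feature_step",
                       forget_bias = 0, checkpoint_steps = NULL,
                       eval_x = NULL, eval_y = NULL) {
  x <- as.matrix(x)
  stopifnot(nrow(x) == length(y))
  features <- colnames(x)
  if (is.null(features)) features <- paste0("x", seq_len(ncol(x)))
  colnames(x) <- features
  input_dim <- if (mode == "per_feature_step") 1L else ncol(x)
  n_steps_seq <- if (mode == "per_feature_step") ncol(x) else 1L

  params <- lstm_params(input_dim, hidden_dim, variant = variant,
                        seed = seed, forget_bias = forget_bias)
  opt <- if (inherits(optimizer, "cp_optimizer")) {
    optimizer
  } else {
    make_optimizer(optimizer, cfg = opt_cfg)
  }

  xs_all <- .encode_batch(as.data.frame(x), features, mode = mode)
  eval_xs <- if (!is.null(eval_x)) {
    ev <- as.matrix(eval_x)
    if (is.null(colnames(ev))) colnames(ev) <- features
    .encode_batch(as.data.frame(ev), features, mode = mode)
  }
  n <- nrow(x)
  batches_per_epoch <- max(1L, ceiling(n / batch_size))
  total_steps <- if (!is.null(max_steps)) {
    as.integer(max_steps)
  } else {
    as.integer(epochs * batches_per_epoch)
  }

  history <- vector("list", total_steps)
  checkpoints <- list()
  step <- 0L
  withr::with_seed(as.integer(seed) + 1L, {
    while (step < total_steps) {
      perm <- sample.int(n)
      for (b in seq_len(batches_per_epoch)) {
        if (step >= total_steps) break
        idx <- perm[(((b - 1L) * batch_size) + 1L):min(b * batch_size, n)]
        xb <- lapply(xs_all, function(m) m[, idx, drop = FALSE])
        fwd <- .lstm_forward_batch(params, xb)
        loss <- bce_loss(fwd$prob, y[idx])
        grads <- lstm_backward(params, fwd, y[idx])
        out <- optimizer_step(opt, params, grads)
        opt <- out$opt
        params <- out$params
        step <- step + 1L
        history[[step]] <- c(step = step, loss = loss)
        if (!is.null(checkpoint_steps) && step %in% checkpoint_steps &&
              !is.null(eval_xs)) {
          ev <- .lstm_forward_batch(params, eval_xs)
          cm <- confusion(eval_y, ev$prob)
          checkpoints[[length(checkpoints) + 1L]] <- tibble::tibble(
            step = step,
            accuracy = (cm$tp + cm$tn) / length(eval_y),
            loss = bce_loss(ev$prob, eval_y)
          )
        }
      }
    }
  })

  structure(list(
    params = params,
    features = features,
    variant = variant,
    mode = mode,
    hidden_dim = hidden_dim,
    optimizer = if (inherits(optimizer, "cp_optimizer")) {
      optimizer$name
    } else {
      optimizer
    },
    seed = as.integer(seed),
    steps = step,
    history = dplyr::bind_rows(lapply(history[seq_len(step)], as.list)),
    checkpoints = if (length(checkpoints)) {
      dplyr::bind_rows(checkpoints)
    } else {
      tibble::tibble(step = integer(), accuracy = numeric(),
                     loss = numeric())
    }
  ), class = "cardio_lstm")
}

#' Predict disease probabilities from a trained model
#'
#' @param object A `cardio_lstm` from [train_lstm()].
#' @param newdata Data frame or matrix containing the model's feature
#'   columns.
#' @param type `"prob"` (default) or `"class"` (threshold 0.5).
#' @param ... Unused.
#' @return Numeric probability vector, or integer 0/1 when
#'   `type = "class"`.
#' @export
predict.cardio_lstm <- function(object, newdata, type = "prob", ...) {
  nd <- as.data.frame(newdata)
  missing <- setdiff(object$features, names(nd))
  if (length(missing) > 0) {
    stop("newdata lacks feature(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  xs <- .encode_batch(nd, object$features, mode = object$mode)
  p <- .lstm_forward_batch(object$params, xs)$prob
  if (type == "class") as.integer(p >= 0.5) else as.numeric(p)
}

#' @export
print.cardio_lstm <- function(x, ...) {
  cat("LSTM risk classifier (", x$variant, " candidate)\n", sep = "")
  cat("  features (", length(x$features), "): ",
      paste(utils::head(x$features, 6), collapse = ", "),
      if (length(x$features) > 6) ", ..." else "", "\n", sep = "")
  cat("  hidden_dim ", x$hidden_dim, ", optimizer ", x$optimizer,
      ", ", x$steps, " steps\n", sep = "")
  if (nrow(x$history) > 0) {
    cat("  final training loss ",
        signif(x$history$loss[nrow(x$history)], 4), "\n", sep = "")
  }
  invisible(x)
}

#' Evaluate a model on labelled data
#'
#' Predicts on `table`, thresholds at `threshold` and returns the full
#' metric report (accuracy, precision, recall, F1, specificity, MCC).
#'
#' @param model A `cardio_lstm`.
#' @param table Data frame with the model features and the label column.
#' @param label Label column name (default `"cardio"`).
#' @param threshold Decision threshold (default 0.5).
#' @return One-row metrics tibble (see [metric_report()]).
#' @export
evaluate_model <- function(model, table, label = "cardio",
                           threshold = 0.5) {
  p <- predict(model, table)
  cm <- confusion(table[[label]], p, threshold = threshold)
  metric_report(cm)
}

#' Save / load a model checkpoint
#'
#' Serialises the trained parameters together with their shapes, cell
#' variant, feature order and seed to a portable JSON checkpoint.
#'
#' @param model A `cardio_lstm`.
#' @param path File path.
#' @return `save_checkpoint()` returns `path` invisibly;
#'   `load_checkpoint()` the restored model (without training history).
#' @export
save_checkpoint <- function(model, path) {
  payload <- list(
    params = lapply(model$params, .array_to_list),
    input_dim = attr(model$params, "input_dim"),
    hidden_dim = model$hidden_dim,
    variant = model$variant,
    mode = model$mode,
    features = model$features,
    optimizer = model$optimizer,
    seed = model$seed,
    steps = model$steps
  )
  jsonlite::write_json(payload, path, digits = I(17), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  pl <- jsonlite::read_json(path, simplifyVector = TRUE)
  params <- lapply(pl$params, .array_from_list)
  attr(params, "input_dim") <- as.integer(pl$input_dim)
  attr(params, "hidden_dim") <- as.integer(pl$hidden_dim)
  attr(params, "variant") <- pl$variant
  class(params) <- "lstm_params"
  structure(list(
    params = params,
    features = pl$features,
    variant = pl$variant,
    mode = pl$mode,
    hidden_dim = as.integer(pl$hidden_dim),
    optimizer = pl$optimizer,
    seed = as.integer(pl$seed),
    steps = as.integer(pl$steps),
    history = tibble::tibble(step = integer(), loss = numeric()),
    checkpoints = tibble::tibble(step = integer(), accuracy = numeric(),
                                 loss = numeric())
  ), class = "cardio_lstm")
}
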