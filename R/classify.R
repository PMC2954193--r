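#' SVM classifier configuration
#'
#' Configuration for the RBF-kernel support-vector classifier
#' `K(u, v) = exp(-gamma * ||u - v||^2)`. A `C` of 0 is accepted for
#' compatibility with published parameter tables but is degenerate for soft
#' margin training, so it maps to the backend's default cost of 1 (the
#' mapping is recorded in the training summary).
#'
#' @param C Regularization parameter (>= 0).
#' @param gamma RBF kernel width (> 0), or `NULL` to use `1 / dimension` at
#'   training time.
#' @return An object of class `svm_config`.
#' @export
svm_config <- function(C = 1, gamma = NULL) {
  stopifnot(length(C) == 1, C >= 0, is.null(gamma) || gamma > 0)
  structure(list(C = C, gamma = gamma, kernel = "RBF"), class = "svm_config")
}

#' Feed-forward network configuration
#'
#' Configuration for a fully-connected network with one hidden layer,
#' trained by vanilla online backpropagation. Activations are set per layer:
#' the input activation is applied elementwise to the features, the hidden
#' and output activations to the respective layer sums. Training runs for
#' `max_cycles` full passes; after every cycle the sum of squared errors
#' (SSE) over the training set is recorded, and the returned network is the
#' snapshot with minimal SSE.
#'
#' @param hidden_units Number of hidden neurons (>= 1).
#' @param activations Length-3 character vector of `"linear"`/`"logistic"`
#'   for the input, hidden and output layers.
#' @param learning_rate Backpropagation step size (default 0.1).
#' @param max_cycles Maximum number of training cycles.
#' @param seed Seed for the random initial weights.
#' @return An object of class `ann_config`.
#' @export
ann_config <- function(hidden_units = 2L,
                       activations = c("linear", "logistic", "logistic"),
                       learning_rate = 0.1,
                       max_cycles = 1000L,
                       seed = 42L) {
  stopifnot(hidden_units >= 1, learning_rate > 0, max_cycles >= 1,
            length(activations) == 3, all(activations %in% c("linear", "logistic")))
  structure(list(hidden_units = as.integer(hidden_units),
                 activations = activations,
                 learning_rate = learning_rate,
                 max_cycles = as.integer(max_cycles),
                 seed = as.integer(seed)),
            class = "ann_config")
}

check_training_input <- function(mat, labels) {
  if (!is.logical(labels) || anyNA(labels)) {
    abort("`labels` must be logical (TRUE = positive class) without NA")
  }
  if (length(labels) != nrow(mat)) {
    abort("labels and feature rows differ in length")
  }
  if (all(labels) || all(!labels)) {
    abort("training data must contain both classes")
  }
}

#' Train an RBF-kernel SVM classifier
#'
#' Fits a soft-margin support-vector classifier with the radial basis
#' function kernel on an encoded feature table. Decision scores are the raw
#' signed distances to the separating hyperplane (no probability scaling);
#' positive scores fall on the positive-class side. Training is
#' deterministic for fixed input.
#'
#' @param features Feature tibble from [encode_features()] (column `id` plus
#'   numeric feature columns), or a plain numeric matrix.
#' @param labels Logical vector, `TRUE` for the positive class.
#' @param config An [svm_config()].
#' @return A fitted model of class `protclass_model`; use [predict()] to
#'   score new sequences, [tidy()]/[glance()] to inspect.
#' @export
train_svm <- function(features, labels, config = svm_config()) {
  stopifnot(inherits(config, "svm_config"))
  mat <- if (is.matrix(features)) features else feature_matrix(features)
  if (any(!is.finite(mat))) abort("non-finite feature value")
  check_training_input(mat, labels)
  cost <- if (config$C == 0) 1 else config$C
  gamma <- config$gamma %||% (1 / ncol(mat))
  yf <- factor(ifelse(labels, "pos", "neg"), levels = c("pos", "neg"))
  # backend-default internal standardization, skipping constant columns
  # (sparse 400-d encodings routinely have all-zero dipeptide columns)
  scale_cols <- apply(mat, 2, stats::var) > 0
  fit <- e1071::svm(x = mat, y = yf, type = "C-classification",
                    kernel = "radial", cost = cost, gamma = gamma,
                    scale = scale_cols)
  structure(list(
    family = "SVM",
    config = config,
    encoding = attr(features, "encoding") %||% NA_character_,
    feature_names = colnames(mat),
    fit = fit,
    default_threshold = 0,
    training_summary = list(C = config$C, cost_used = cost, gamma = gamma,
                            n_support = fit$tot.nSV, n = nrow(mat))
  ), class = c("protclass_svm", "protclass_model"))
}

activation_fn <- function(name) {
  if (name == "logistic") function(z) 1 / (1 + exp(-z)) else identity
}
activation_deriv <- function(name, out) {
  if (name == "logistic") out * (1 - out) else rep(1, length(out))
}

#' Train a feed-forward neural network classifier
#'
#' Trains a fully-connected one-hidden-layer network by vanilla online
#' backpropagation against 1/0 targets (positive/negative). The SSE over the
#' training set is monitored after every cycle; the returned network is the
#' weight snapshot at the cycle where SSE was least, and the full SSE trace
#' is kept in the training summary. Identical data, configuration and seed
#' give an identical trace and model.
#'
#' @inheritParams train_svm
#' @param config An [ann_config()].
#' @return A fitted model of class `protclass_model`.
#' @export
train_ann <- function(features, labels, config = ann_config()) {
  stopifnot(inherits(config, "ann_config"))
  mat <- if (is.matrix(features)) features else feature_matrix(features)
  if (any(!is.finite(mat))) abort("non-finite feature value")
  check_training_input(mat, labels)

  f_in <- activation_fn(config$activations[1])
  f_hid <- activation_fn(config$activations[2])
  f_out <- activation_fn(config$activations[3])
  X <- f_in(mat)
  y <- as.numeric(labels)
  n <- nrow(X); d <- ncol(X); h <- config$hidden_units; lr <- config$learning_rate

  init <- with_local_seed(config$seed, {
    list(W1 = matrix(runif((d + 1) * h, -0.5, 0.5), nrow = d + 1),
         W2 = matrix(runif(h + 1, -0.5, 0.5), ncol = 1))
  })
  W1 <- init$W1; W2 <- init$W2

  forward_all <- function(W1, W2) {
    H <- f_hid(cbind(1, X) %*% W1)
    as.numeric(f_out(cbind(1, H) %*% W2))
  }

  sse_trace <- numeric(config$max_cycles)
  best <- list(sse = Inf, W1 = W1, W2 = W2, cycle = 0L)
  for (cycle in seq_len(config$max_cycles)) {
    for (i in seq_len(n)) {
      xi <- c(1, X[i, ])
      hid <- as.numeric(f_hid(xi %*% W1))
      out <- as.numeric(f_out(c(1, hid) %*% W2))
      delta_out <- (out - y[i]) * activation_deriv(config$activations[3], out)
      delta_hid <- (W2[-1, 1] * delta_out) * activation_deriv(config$activations[2], hid)
      W2 <- W2 - lr * delta_out * cbind(c(1, hid))
      W1 <- W1 - lr * outer(xi, delta_hid)
    }
    sse <- sum((forward_all(W1, W2) - y)^2)
    if (!is.finite(sse)) {
      abort(paste0("ANN training diverged (non-finite SSE) at cycle ", cycle))
    }
    sse_trace[cycle] <- sse
    if (sse < best$sse) {
      best <- list(sse = sse, W1 = W1, W2 = W2, cycle = cycle)
    }
  }

  structure(list(
    family = "ANN",
    config = config,
    encoding = attr(features, "encoding") %||% NA_character_,
    feature_names = colnames(mat),
    fit = list(W1 = best$W1, W2 = best$W2),
    default_threshold = 0.5,
    training_summary = list(sse_trace = sse_trace, best_sse = best$sse,
                            best_cycle = best$cycle, n = n)
  ), class = c("protclass_ann", "protclass_model"))
}

#' @export
print.protclass_model <- function(x, ...) {
  cat(sprintf("<protclass_model> %s on %s features (%d-d), n = %d\n",
              x$family, x$encoding, length(x$feature_names),
              x$training_summary$n))
  if (x$family == "SVM") {
    cat(sprintf("  C = %g (cost used %g), gamma = %g, support vectors = %d\n",
                x$config$C, x$training_summary$cost_used,
                x$training_summary$gamma, x$training_summary$n_support))
  } else {
    cat(sprintf("  hidden = %d, lr = %g, best SSE %.4f at cycle %d/%d\n",
                x$config$hidden_units, x$config$learning_rate,
                x$training_summary$best_sse, x$training_summary$best_cycle,
                x$config$max_cycles))
  }
  invisible(x)
}

# Internal: raw decision scores for a feature matrix.
model_scores <- function(model, mat) {
  if (length(model$feature_names) != ncol(mat) ||
      (!is.null(colnames(mat)) && !identical(colnames(mat), model$feature_names))) {
    abort(paste0("feature dimension mismatch: model expects ",
                 length(model$feature_names), " columns (",
                 model$encoding, "), got ", ncol(mat)))
  }
  if (nrow(mat) == 0) return(numeric(0))
  if (model$family == "SVM") {
    pred <- predict(model$fit, mat, decision.values = TRUE)
    dv <- attr(pred, "decision.values")
    # the backend orients the decision value toward whichever class it met
    # first in the training rows; the column name records that orientation
    if (identical(colnames(dv), "neg/pos")) -as.numeric(dv) else as.numeric(dv)
  } else {
    f_in <- activation_fn(model$config$activations[1])
    f_hid <- activation_fn(model$config$activations[2])
    f_out <- activation_fn(model$config$activations[3])
    H <- f_hid(cbind(1, f_in(mat)) %*% model$fit$W1)
    as.numeric(f_out(cbind(1, H) %*% model$fit$W2))
  }
}

#' Score sequences with a trained classifier
#'
#' Computes the continuous decision score for every row of an encoded
#' feature table and thresholds it into a binary call with the rule
#' `label = (score >= threshold)`. SVM scores are signed margins (default
#' threshold 0); network outputs lie in `[0, 1]` (default threshold 0.5).
#'
#' @param object A `protclass_model` from [train_svm()] or [train_ann()].
#' @param features Feature tibble from [encode_features()], with the same
#'   encoding the model was trained on.
#' @param threshold Decision threshold; defaults to the family default.
#' @param ... Unused.
#' @return A tibble with columns `id`, `score`, `label`, `threshold`; one
#'   row per input row (empty input gives an empty table).
#' @export
predict.protclass_model <- function(object, features, threshold = NULL, ...) {
  threshold <- threshold %||% object$default_threshold
  stopifnot(is.numeric(threshold), length(threshold) == 1)
  mat <- if (is.matrix(features)) features else feature_matrix(features)
  ids <- if (is.data.frame(features) && "id" %in% names(features)) {
    features$id
  } else {
    as.character(seq_len(nrow(mat)))
  }
  scores <- model_scores(object, mat)
  tibble(id = ids, score = scores, label = scores >= threshold,
         threshold = rep(threshold, length(scores)))
}

#' Save or load a trained classifier
#'
#' Persists a model as a single self-describing file (format version, family,
#' configuration, encoding name and fitted state).
#'
#' @param model A `protclass_model`.
#' @param path File path.
#' @return `write_model()` returns `path` invisibly; `read_model()` the
#'   restored model.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "protclass_model"))
  saveRDS(list(format = "protclass_model", version = 1L, model = model), path)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "protclass_model")) {
    abort(paste0("not a protclass model file: ", path))
  }
  obj$model
}
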