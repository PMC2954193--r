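#' Tidy a cross-validation result
#'
#' `tidy()` returns the per-threshold metrics table; `glance()` a one-row
#' summary of the selected operating point plus the held-out AUC.
#'
#' @param x A `protclass_cv` from [loocv()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.protclass_cv <- function(x, ...) {
  x$threshold_table
}

#' @rdname tidy.protclass_cv
#' @export
glance.protclass_cv <- function(x, ...) {
  b <- x$best
  tibble(
    family = x$family, encoding = x$encoding, n = x$n,
    threshold = b$threshold, sensitivity = b$sensitivity,
    specificity = b$specificity, accuracy = b$accuracy,
    mcc = b$mcc, ppv = b$ppv, auc = x$roc$auc
  )
}

#' Tidy an ROC curve
#'
#' `tidy()` returns the curve points; `glance()` the AUC and class sizes.
#'
#' @param x A `protclass_roc` from [roc_curve()].
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.protclass_roc <- function(x, ...) {
  x$points
}

#' @rdname tidy.protclass_roc
#' @export
glance.protclass_roc <- function(x, ...) {
  tibble(auc = x$auc, n_pos = x$n_pos, n_neg = x$n_neg)
}

#' Tidy a trained classifier
#'
#' `tidy()` returns the model's hyperparameters as name/value rows;
#' `glance()` a one-row training summary (for networks this includes the
#' minimal SSE and the cycle where it was reached).
#'
#' @param x A `protclass_model`.
#' @param ... Unused.
#' @return A tibble.
#' @export
tidy.protclass_model <- function(x, ...) {
  params <- if (x$family == "SVM") {
    list(C = x$config$C, cost_used = x$training_summary$cost_used,
         gamma = x$training_summary$gamma)
  } else {
    list(hidden_units = x$config$hidden_units,
         learning_rate = x$config$learning_rate,
         max_cycles = x$config$max_cycles, seed = x$config$seed)
  }
  tibble(term = names(params), value = as.numeric(unlist(params)))
}

#' @rdname tidy.protclass_model
#' @export
glance.protclass_model <- function(x, ...) {
  if (x$family == "SVM") {
    tibble(family = "SVM", encoding = x$encoding,
           dimension = length(x$feature_names),
           n = x$training_summary$n,
           n_support = x$training_summary$n_support)
  } else {
    tibble(family = "ANN", encoding = x$encoding,
           dimension = length(x$feature_names),
           n = x$training_summary$n,
           best_sse = x$training_summary$best_sse,
           best_cycle = x$training_summary$best_cycle)
  }
}

#' Plot an ROC curve
#'
#' Step plot of the ROC points with the chance diagonal; the AUC is shown in
#' the subtitle.
#'
#' @param object A `protclass_roc` or `protclass_cv`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.protclass_roc <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(colour = "steelblue", linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)",
      title = "ROC curve",
      subtitle = sprintf("AUC = %.3f (%d positives, %d negatives)",
                         object$auc, object$n_pos, object$n_neg)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a threshold scan
#'
#' Sensitivity, specificity and accuracy as a function of the decision
#' threshold, with the selected best threshold marked.
#'
#' @param object A `protclass_cv` from [loocv()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.protclass_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$threshold_table[, c("threshold", "sensitivity", "specificity", "accuracy")],
    cols = -"threshold", names_to = "metric", values_to = "percent"
  )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$threshold, y = .data$percent,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best$threshold, linetype = "dotted") +
    ggplot2::labs(
      x = "Decision threshold", y = "Percent", colour = NULL,
      title = sprintf("%s / %s leave-one-out threshold scan (n = %d)",
                      object$family, object$encoding, object$n),
      subtitle = sprintf("best threshold %+.2f: accuracy %.2f%%",
                         object$best$threshold, object$best$accuracy)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a network training trace
#'
#' Per-cycle sum of squared errors for a trained network, with the retained
#' minimal-SSE cycle marked.
#'
#' @param object A `protclass_model` of the ANN family.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.protclass_model <- function(object, ...) {
  if (object$family != "ANN") {
    abort("autoplot is available for ANN models (SSE trace); SVM models have no trace")
  }
  trace <- tibble(cycle = seq_along(object$training_summary$sse_trace),
                  sse = object$training_summary$sse_trace)
  ggplot2::ggplot(trace, ggplot2::aes(x = .data$cycle, y = .data$sse)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_vline(xintercept = object$training_summary$best_cycle,
                        linetype = "dotted") +
    ggplot2::labs(x = "Training cycle", y = "Sum of squared errors",
                  title = "Network training trace",
                  subtitle = sprintf("minimal SSE %.4f at cycle %d",
                                     object$training_summary$best_sse,
                                     object$training_summary$best_cycle)) +
    ggplot2::theme_minimal()
}
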