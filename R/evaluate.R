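#' Fourfold confusion counts
#'
#' Standard confusion counts for a binary problem: TP (true positives), FP,
#' TN, FN, with `TRUE` the positive class.
#'
#' @param truth,predicted Equal-length logical vectors.
#' @return A one-row tibble with columns `tp`, `fp`, `tn`, `fn`.
#' @export
confusion <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    abort("truth and predicted differ in length")
  }
  if (length(truth) == 0) abort("empty label vectors")
  if (!is.logical(truth) || !is.logical(predicted) || anyNA(truth) || anyNA(predicted)) {
    abort("labels must be logical (TRUE = positive) without NA")
  }
  tibble(
    tp = sum(truth & predicted),
    fp = sum(!truth & predicted),
    tn = sum(!truth & !predicted),
    fn = sum(truth & !predicted)
  )
}

#' Performance metrics from confusion counts
#'
#' Computes the five standard measures from a fourfold table:
#' sensitivity `100 * TP / (TP + FN)` (percent of positives recovered),
#' specificity `100 * TN / (TN + FP)`, accuracy
#' `100 * (TP + TN) / total`, Matthews correlation coefficient
#' `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, and positive
#' predictive value `TP / (TP + FP)`. All values are kept at full precision;
#' rounding is left to presentation. Degenerate denominators are flagged
#' rather than propagated: a zero MCC denominator yields `mcc = 0` with
#' `mcc_degenerate = TRUE`, and `TP + FP = 0` yields `ppv = NA` with
#' `ppv_undefined = TRUE`.
#'
#' @param counts A one-row confusion tibble from [confusion()] (or any data
#'   frame with columns `tp`, `fp`, `tn`, `fn`).
#' @param threshold Optional decision threshold to record alongside the
#'   metrics.
#' @return A one-row tibble: `threshold`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `accuracy` (percent), `mcc`, `ppv`, and
#'   the two degeneracy flags.
#' @examples
#' classifier_metrics(tibble::tibble(tp = 49, fn = 7, tn = 273, fp = 27))
#' @export
classifier_metrics <- function(counts, threshold = NA_real_) {
  stopifnot(is.data.frame(counts), all(c("tp", "fp", "tn", "fn") %in% names(counts)),
            nrow(counts) == 1)
  tp <- counts$tp; fp <- counts$fp; tn <- counts$tn; fn <- counts$fn
  if (any(c(tp, fp, tn, fn) < 0)) abort("confusion counts must be non-negative")
  total <- tp + fp + tn + fn

  sn <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  sp <- if (tn + fp > 0) 100 * tn / (tn + fp) else NA_real_
  acc <- 100 * (tp + tn) / total

  mcc_den <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc_degenerate <- mcc_den == 0
  mcc <- if (mcc_degenerate) 0 else (tp * tn - fp * fn) / mcc_den

  ppv_undefined <- (tp + fp) == 0
  ppv <- if (ppv_undefined) NA_real_ else tp / (tp + fp)

  tibble(threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
         sensitivity = sn, specificity = sp, accuracy = acc,
         mcc = mcc, ppv = ppv,
         mcc_degenerate = mcc_degenerate, ppv_undefined = ppv_undefined)
}

#' Metrics across a grid of decision thresholds
#'
#' Applies the rule `predicted = (score >= threshold)` at every threshold of
#' an evenly spaced grid and computes [classifier_metrics()] for each. The
#' default grid runs from -1.0 to 1.0 in steps of 0.1 (21 thresholds),
#' matching the span of SVM margin scores near the decision boundary.
#'
#' @param scores Numeric decision scores.
#' @param labels Logical truth vector, aligned with `scores`.
#' @param start,stop,step Grid definition; `step` must be positive.
#' @return A tibble with one metrics row per threshold, in grid order.
#' @export
threshold_scan <- function(scores, labels, start = -1, stop = 1, step = 0.1) {
  if (step <= 0) abort("`step` must be positive")
  if (length(scores) != length(labels)) abort("scores and labels differ in length")
  grid <- seq(start, stop, by = step)
  purrr::map_dfr(grid, function(th) {
    classifier_metrics(confusion(labels, scores >= th), threshold = th)
  })
}

#' Select the best threshold row
#'
#' Picks the row maximizing accuracy; ties are broken by the smallest
#' sensitivity-specificity gap, then by the lower threshold. This follows
#' the usual model-selection rule of maximizing accuracy while keeping
#' sensitivity and specificity nearly equal where possible.
#'
#' @param table A metrics table from [threshold_scan()].
#' @return The selected one-row tibble.
#' @export
select_best <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) >= 1)
  ranked <- dplyr::arrange(table,
                           dplyr::desc(.data$accuracy),
                           abs(.data$sensitivity - .data$specificity),
                           .data$threshold)
  ranked[1, ]
}

#' ROC curve and AUC
#'
#' Builds the receiver operating characteristic curve from continuous
#' decision scores: one step per distinct score value (ties grouped),
#' sweeping the cut-point from above the maximum score down, with endpoints
#' (0, 0) and (1, 1). The area under the curve is computed by the
#' trapezoidal rule, which equals the Mann-Whitney U statistic divided by
#' `n_pos * n_neg`. AUC is invariant under any strictly increasing transform
#' of the scores.
#'
#' @param scores Numeric decision scores.
#' @param labels Logical truth vector; both classes must be present.
#' @return An object of class `protclass_roc`: a list with `points` (tibble
#'   of `cutoff`, `fpr`, `tpr`) and `auc`.
#' @export
roc_curve <- function(scores, labels) {
  if (length(scores) != length(labels)) abort("scores and labels differ in length")
  if (!is.logical(labels) || anyNA(labels)) abort("labels must be logical without NA")
  if (all(labels) || all(!labels)) abort("ROC requires both classes present")
  n_pos <- sum(labels); n_neg <- sum(!labels)
  cuts <- sort(unique(scores), decreasing = TRUE)
  tpr <- vapply(cuts, function(c) sum(scores >= c & labels) / n_pos, numeric(1))
  fpr <- vapply(cuts, function(c) sum(scores >= c & !labels) / n_neg, numeric(1))
  points <- tibble(cutoff = c(Inf, cuts), fpr = c(0, fpr), tpr = c(0, tpr))
  if (points$fpr[nrow(points)] < 1 || points$tpr[nrow(points)] < 1) {
    points <- dplyr::bind_rows(points, tibble(cutoff = -Inf, fpr = 1, tpr = 1))
  }
  auc <- sum(diff(points$fpr) * (head(points$tpr, -1) + tail(points$tpr, -1)) / 2)
  structure(list(points = points, auc = auc,
                 n_pos = n_pos, n_neg = n_neg),
            class = "protclass_roc")
}

#' @export
print.protclass_roc <- function(x, ...) {
  cat(sprintf("<protclass_roc> %d positives / %d negatives, AUC = %.4f\n",
              x$n_pos, x$n_neg, x$auc))
  invisible(x)
}

#' Leave-one-out cross-validation
#'
#' Runs the full evaluation protocol: each sequence is held out exactly once
#' while a model is trained on the remaining `n - 1`, the held-out decision
#' score is recorded, and the collected scores are swept over a threshold
#' grid to produce the per-threshold metrics table, the selected best row,
#' and the ROC curve on held-out scores.
#'
#' Encodings are computed once per sequence before splitting: every encoding
#' here is a function of a single sequence (and its own profile), so no
#' information leaks between folds. For the network family the weight
#' initialization seed is offset by the fold index, making the whole CV
#' reproducible.
#'
#' @param data Labeled sequence tibble (columns `id`, `residues`, logical
#'   `label`), e.g. from [read_labeled_fasta()] or [simulate_sequences()];
#'   at least two members per class.
#' @param encoding Encoding name passed to [encode_features()].
#' @param config An [svm_config()] or [ann_config()].
#' @param profiles Named list of profiles for `encoding = "PSSM400"`.
#' @param gap Gap width for `encoding = "GAP1"`.
#' @param start,stop,step Threshold grid for [threshold_scan()].
#' @return An object of class `protclass_cv`: list with `scores` (tibble
#'   `id`, `label`, `score`), `threshold_table`, `best`, `roc`, `encoding`,
#'   `family`, `config`, `n`.
#' @export
loocv <- function(data, encoding, config = svm_config(),
                  profiles = NULL, gap = 1L,
                  start = -1, stop = 1, step = 0.1) {
  check_labeled_dataset(data, min_per_class = 2L)
  features <- encode_features(data, encoding = encoding, gap = gap, profiles = profiles)
  mat <- feature_matrix(features)
  labels <- data$label
  n <- nrow(mat)

  family <- if (inherits(config, "svm_config")) "SVM"
            else if (inherits(config, "ann_config")) "ANN"
            else abort("`config` must be an svm_config() or ann_config()")

  held_out <- vapply(seq_len(n), function(i) {
    train_lab <- labels[-i]
    if (all(train_lab) || all(!train_lab)) {
      abort(paste0("fold ", i, ": training split is single-class; ",
                   "dataset too small or imbalanced for LOO"))
    }
    model <- if (family == "SVM") {
      train_svm(mat[-i, , drop = FALSE], train_lab, config)
    } else {
      fold_config <- config
      fold_config$seed <- config$seed + i
      train_ann(mat[-i, , drop = FALSE], train_lab, fold_config)
    }
    model_scores(model, mat[i, , drop = FALSE])
  }, numeric(1))

  table <- threshold_scan(held_out, labels, start = start, stop = stop, step = step)
  structure(list(
    scores = tibble(id = data$id, label = labels, score = held_out),
    threshold_table = table,
    best = select_best(table),
    roc = roc_curve(held_out, labels),
    encoding = encoding,
    family = family,
    config = config,
    n = n
  ), class = "protclass_cv")
}

#' @export
print.protclass_cv <- function(x, ...) {
  b <- x$best
  cat(sprintf("<protclass_cv> %s on %s, n = %d (LOO)\n", x$family, x$encoding, x$n))
  cat(sprintf("  best threshold %+.2f: ACC %.2f%%, SN %.2f%%, SP %.2f%%, MCC %.2f, PPV %s\n",
              b$threshold, b$accuracy, b$sensitivity, b$specificity, b$mcc,
              ifelse(is.na(b$ppv), "NA", sprintf("%.2f", b$ppv))))
  cat(sprintf("  held-out ROC AUC %.4f\n", x$roc$auc))
  invisible(x)
}

#' Export a threshold table or ROC curve as TSV
#'
#' `write_threshold_tsv()` writes one row per scanned threshold with columns
#' `threshold`, `sensitivity`, `specificity`, `accuracy`, `mcc`, `ppv`;
#' `write_roc_tsv()` writes the ROC points (`cutoff`, `fpr`, `tpr`).
#'
#' @param cv A `protclass_cv` (or a metrics table for
#'   `write_threshold_tsv()`, a `protclass_roc` for `write_roc_tsv()`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_threshold_tsv <- function(cv, path) {
  table <- if (inherits(cv, "protclass_cv")) cv$threshold_table else cv
  out <- table[, c("threshold", "sensitivity", "specificity", "accuracy", "mcc", "ppv")]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_threshold_tsv
#' @export
write_roc_tsv <- function(cv, path) {
  roc <- if (inherits(cv, "protclass_cv")) cv$roc else cv
  utils::write.table(roc$points, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
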