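test_that("confusion computes the standard fourfold counts", {
  truth <- rep(c(TRUE, FALSE), each = 5)
  all_correct <- confusion(truth, truth)
  expect_equal(as.list(all_correct), list(tp = 5L, fp = 0L, tn = 5L, fn = 0L))
  all_flipped <- confusion(truth, !truth)
  expect_equal(as.list(all_flipped), list(tp = 0L, fp = 5L, tn = 0L, fn = 5L))

  # 48 positives, 45 recovered
  truth48 <- rep(c(TRUE, FALSE), c(48, 308))
  pred <- truth48; pred[1:3] <- FALSE
  cc <- confusion(truth48, pred)
  expect_equal(cc$tp, 45)
  expect_equal(cc$fn, 3)
  expect_equal(cc$tp + cc$fn, 48)

  expect_error(confusion(truth, truth[-1]), "length")
  expect_error(confusion(c(1, 0), c(TRUE, FALSE)), "logical")
})

test_that("classifier_metrics reproduces hand-computed values", {
  m <- classifier_metrics(tibble::tibble(tp = 49, fn = 7, tn = 273, fp = 27))
  expect_equal(m$sensitivity, 100 * 49 / 56)
  expect_equal(m$specificity, 100 * 273 / 300)
  expect_equal(m$accuracy, 100 * 322 / 356)
  expect_equal(m$ppv, 49 / 76)
  den <- sqrt(prod(c(49 + 27, 49 + 7, 273 + 27, 273 + 7)))
  expect_equal(m$mcc, (49 * 273 - 27 * 7) / den)

  perfect <- classifier_metrics(tibble::tibble(tp = 10, tn = 10, fp = 0, fn = 0))
  expect_equal(perfect$mcc, 1)
  expect_equal(perfect$accuracy, 100)
})

test_that("degenerate denominators are flagged, not propagated", {
  all_neg <- classifier_metrics(tibble::tibble(tp = 0, fp = 0, tn = 5, fn = 5))
  expect_true(all_neg$mcc_degenerate)
  expect_equal(all_neg$mcc, 0)
  expect_true(all_neg$ppv_undefined)
  expect_true(is.na(all_neg$ppv))
  ok <- classifier_metrics(tibble::tibble(tp = 3, fp = 1, tn = 4, fn = 2))
  expect_false(ok$mcc_degenerate || ok$ppv_undefined)
})

test_that("threshold_scan sweeps the grid with the score >= threshold rule", {
  withr::with_seed(19, {
    scores <- c(rnorm(20, 0.5), rnorm(30, -0.5))
    labels <- rep(c(TRUE, FALSE), c(20, 30))
  })
  scan <- threshold_scan(scores, labels)
  expect_equal(nrow(scan), 21)
  expect_equal(scan$threshold, seq(-1, 1, 0.1))

  below <- threshold_scan(scores, labels, start = min(scores) - 1,
                          stop = min(scores) - 1, step = 1)
  expect_equal(below$sensitivity, 100)
  expect_equal(below$specificity, 0)
  above <- threshold_scan(scores, labels, start = max(scores) + 1,
                          stop = max(scores) + 1, step = 1)
  expect_equal(above$sensitivity, 0)
  expect_equal(above$specificity, 100)

  # reported metrics are consistent with the reported counts
  for (i in c(1, 11, 21)) {
    r <- scan[i, ]
    expect_equal(r$sensitivity, 100 * r$tp / (r$tp + r$fn))
    expect_equal(r$specificity, 100 * r$tn / (r$tn + r$fp))
    expect_equal(r$tp + r$fn, 20)
    expect_equal(r$tn + r$fp, 30)
  }
  expect_error(threshold_scan(scores, labels, step = 0), "positive")
})

test_that("select_best maximizes accuracy with the declared tie-breaks", {
  single <- classifier_metrics(tibble::tibble(tp = 3, fp = 1, tn = 4, fn = 2), 0.1)
  expect_equal(select_best(single), single)

  tied <- tibble::tibble(
    threshold = c(-0.5, 0, 0.5),
    sensitivity = c(90, 84, 70), specificity = c(80, 86, 100),
    accuracy = c(85, 85, 80), mcc = 0, ppv = 0.5
  )
  expect_equal(select_best(tied)$threshold, 0)  # gap 2 beats gap 10

  tied2 <- tibble::tibble(
    threshold = c(0.2, -0.3),
    sensitivity = c(85, 85), specificity = c(85, 85),
    accuracy = c(85, 85), mcc = 0, ppv = 0.5
  )
  expect_equal(select_best(tied2)$threshold, -0.3)  # lower threshold wins

  # exhaustive argmax oracle on a synthetic scan
  withr::with_seed(23, {
    scores <- runif(60, -1, 1); labels <- runif(60) < 0.4
  })
  scan <- threshold_scan(scores, labels)
  best <- select_best(scan)
  ord <- order(-scan$accuracy, abs(scan$sensitivity - scan$specificity), scan$threshold)
  expect_equal(best, scan[ord[1], ])
})

test_that("roc_curve yields AUC 1 for separated scores and ~0.5 for noise", {
  sep <- roc_curve(c(5, 4, 3, -3, -4, -5), rep(c(TRUE, FALSE), each = 3))
  expect_equal(sep$auc, 1)
  expect_equal(sep$points$fpr[1], 0)
  expect_equal(sep$points$tpr[nrow(sep$points)], 1)
  expect_true(all(diff(sep$points$fpr) >= 0) && all(diff(sep$points$tpr) >= 0))

  withr::with_seed(29, {
    scores <- rnorm(2000)
    labels <- runif(2000) < 0.3
  })
  expect_equal(roc_curve(scores, labels)$auc, 0.5, tolerance = 0.05)

  expect_error(roc_curve(1:3, rep(TRUE, 3)), "both classes")
})

test_that("AUC equals the rank-statistic (Mann-Whitney) identity, ties included", {
  scores <- c(3.1, 2.5, 2.5, 1.0, 0.4, 2.5, 1.0, 0.2, -1, -2)
  labels <- rep(c(TRUE, FALSE), each = 5)
  n_pos <- 5; n_neg <- 5
  u <- sum(rank(scores)[labels]) - n_pos * (n_pos + 1) / 2
  expect_equal(roc_curve(scores, labels)$auc, u / (n_pos * n_neg))
})

test_that("AUC is invariant under strictly monotone score transforms", {
  withr::with_seed(41, {
    scores <- rnorm(80)
    labels <- runif(80) < 0.5
  })
  base <- roc_curve(scores, labels)$auc
  expect_equal(roc_curve(exp(scores), labels)$auc, base)
  expect_equal(roc_curve(2 * scores + 7, labels)$auc, base)
})

test_that("roc_curve agrees with an established ROC implementation", {
  skip_if_not_installed("pROC")
  withr::with_seed(43, {
    scores <- rnorm(120) + rep(c(1, 0), c(40, 80))
    labels <- rep(c(TRUE, FALSE), c(40, 80))
  })
  ours <- roc_curve(scores, labels)$auc
  ref <- as.numeric(pROC::auc(pROC::roc(labels, scores, quiet = TRUE,
                                        direction = "<")))
  expect_equal(ours, ref)
})

test_that("loocv holds out every sequence exactly once", {
  data <- toy_dataset(n_pos = 5, n_neg = 5, len = 60)
  cv <- loocv(data, "AAC", svm_config())
  expect_equal(nrow(cv$scores), 10)
  expect_setequal(cv$scores$id, data$id)
  expect_equal(nrow(cv$threshold_table), 21)
  expect_s3_class(cv$best, "data.frame")
  expect_equal(cv$n, 10)
  expect_error(loocv(data[c(1, 7:10), ], "AAC", svm_config()), "each class")
})

test_that("loocv held-out SVM scores are invariant to dataset order", {
  data <- toy_dataset(n_pos = 6, n_neg = 6, len = 60)
  cv1 <- loocv(data, "AAC", svm_config())
  withr::with_seed(2, perm <- sample(nrow(data)))
  cv2 <- loocv(data[perm, ], "AAC", svm_config())
  merged <- merge(cv1$scores, cv2$scores, by = "id")
  expect_equal(merged$score.x, merged$score.y, tolerance = 1e-2)
})

test_that("cv results expose tidy, glance and TSV/ROC export", {
  data <- toy_dataset(n_pos = 5, n_neg = 5, len = 60)
  cv <- loocv(data, "AAC", svm_config())
  expect_equal(tidy(cv), cv$threshold_table)
  g <- glance(cv)
  expect_equal(g$n, 10)
  expect_equal(g$auc, cv$roc$auc)

  f1 <- withr::local_tempfile(); f2 <- withr::local_tempfile()
  write_threshold_tsv(cv, f1)
  tab <- read.delim(f1)
  expect_equal(nrow(tab), 21)
  expect_named(tab, c("threshold", "sensitivity", "specificity", "accuracy", "mcc", "ppv"))
  write_roc_tsv(cv, f2)
  expect_named(read.delim(f2), c("cutoff", "fpr", "tpr"))
})

test_that("autoplot methods return ggplot objects", {
  data <- toy_dataset(n_pos = 5, n_neg = 5, len = 60)
  cv <- loocv(data, "AAC", svm_config())
  expect_s3_class(autoplot(cv), "ggplot")
  expect_s3_class(autoplot(cv$roc), "ggplot")
  ann <- train_ann(as.matrix(expand.grid(f1 = 0:1, f2 = 0:1)),
                   c(FALSE, FALSE, FALSE, TRUE),
                   ann_config(max_cycles = 50, seed = 1))
  expect_s3_class(autoplot(ann), "ggplot")
})
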