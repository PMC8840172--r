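test_that("targets binarize at their cutoff with the favorable boundary", {
  yield_spec <- target_spec("yield", 16, "high-is-good")
  expect_equal(binarize_target(c(27.0, 16, 15.9), yield_spec),
               c("high", "high", "low"))
  tta_spec <- target_spec("tta", 0.9, "low-is-good")
  expect_equal(binarize_target(c(1.2, 0.9, 0.8), tta_spec),
               c("low", "high", "high"))
  expect_error(target_spec("x", Inf), "finite")
  expect_error(target_spec("x", 1, "sideways"))
  expect_error(binarize_target(c(1, NA), yield_spec), "missing")
})

test_that("stratified folds are balanced, seeded, and order invariant", {
  set.seed(2)
  x <- data.frame(a = rnorm(80), b = rnorm(80))
  labels <- rep(c("high", "low"), c(60, 20))
  keys <- sprintf("plot%03d", 1:80)
  cv <- cross_validate(x, labels, classifier_spec("knn", cv_folds = 10,
                                                  cv_seed = 5), keys = keys)
  expect_equal(as.vector(table(cv$fold)), rep(8, 10))
  # class proportions per fold within one specimen of global proportion
  per_fold_high <- tapply(cv$labels == "high", cv$fold, sum)
  expect_true(all(per_fold_high == 6))

  # permuting row order leaves per-specimen predictions unchanged
  perm <- sample(80)
  cv2 <- cross_validate(x[perm, ], labels[perm],
                        classifier_spec("knn", cv_folds = 10, cv_seed = 5),
                        keys = keys[perm])
  expect_equal(cv2$predicted[order(perm)], cv$predicted)
  expect_equal(cv2$score[order(perm)], cv$score)

  # rerunning is deterministic
  cv3 <- cross_validate(x, labels, classifier_spec("knn", cv_folds = 10,
                                                   cv_seed = 5), keys = keys)
  expect_identical(cv3$predicted, cv$predicted)
})

test_that("degenerate and separable feature sets behave as expected", {
  # two distant Gaussian blobs are perfectly separated by 1-NN
  set.seed(9)
  x <- rbind(matrix(rnorm(60, 0), ncol = 2),
             matrix(rnorm(60, 20), ncol = 2))
  labels <- rep(c("high", "low"), each = 30)
  cv <- cross_validate(as.data.frame(x), labels,
                       classifier_spec("knn", k = 1, cv_folds = 10))
  expect_equal(mean(cv$predicted == labels), 1.0)

  # identical features for all specimens: constant majority prediction
  xc <- data.frame(a = rep(1, 40), b = rep(2, 40))
  labc <- rep(c("high", "low"), c(28, 12))
  cvc <- cross_validate(xc, labc, classifier_spec("knn", cv_folds = 4))
  expect_true(all(cvc$predicted == "high"))

  # classes smaller than the fold count reduce folds with a warning
  small <- rep(c("high", "low"), c(36, 4))
  expect_warning(
    cv_small <- cross_validate(data.frame(a = rnorm(40)), small,
                               classifier_spec("knn", cv_folds = 10)),
    "reducing folds")
  expect_equal(max(cv_small$fold), 4)
})

test_that("confusion cells follow the high/low norm-population convention", {
  p <- confusion_partition(c("high", "high", "low", "low"),
                           c("high", "low", "low", "high"))
  expect_equal(c(p$TN, p$TP, p$FN, p$FP), c(1, 1, 1, 1))
  expect_equal(p$index$TN, 1L)  # high predicted AND high actual
  expect_equal(p$index$FP, 2L)  # low predicted, high actual
  expect_equal(p$index$TP, 3L)  # low predicted, low actual
  expect_equal(p$index$FN, 4L)  # high predicted, low actual

  all_ok <- confusion_partition(rep(c("high", "low"), 5),
                                rep(c("high", "low"), 5))
  expect_equal(all_ok$FN + all_ok$FP, 0)

  allh <- confusion_partition(rep("high", 58), rep("high", 58))
  expect_equal(allh$TN, 58)
  expect_equal(allh$TP + allh$FN + allh$FP, 0)
  expect_error(confusion_partition("high", c("high", "low")), "equal length")
  expect_error(confusion_partition("yes", "no"), "high")
})

test_that("classification accuracy equals its complement identity", {
  set.seed(31)
  for (i in 1:20) {
    n <- sample(20:100, 1)
    actual <- sample(c("high", "low"), n, replace = TRUE)
    predicted <- sample(c("high", "low"), n, replace = TRUE)
    p <- confusion_partition(actual, predicted)
    expect_equal(classification_accuracy(p),
                 1 - (p$FN + p$FP) / p$n_total)
  }
  expect_error(classification_accuracy(list(TN = 0, TP = 0, FN = 0,
                                            FP = 0)), "empty")
})

test_that("rank-based AUC matches pair counting and handles ties", {
  labels <- c("high", "high", "low", "low")
  expect_equal(auc(c(1, 1, 0, 0), labels), 1.0)

  # worked set with one tie: brute-force over all (high, low) pairs
  scores <- c(0.9, 0.4, 0.4, 0.1)
  pairs <- expand.grid(hi = scores[1:2], lo = scores[3:4])
  brute <- mean(ifelse(pairs$hi > pairs$lo, 1,
                       ifelse(pairs$hi == pairs$lo, 0.5, 0)))
  expect_equal(auc(scores, labels), brute)

  # agrees with an independent ROC implementation on random data
  skip_if_not_installed("pROC")
  set.seed(17)
  s <- rnorm(60); lab <- sample(c("high", "low"), 60, replace = TRUE)
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = factor(lab, levels = c("low", "high")), predictor = s,
    direction = "<", quiet = TRUE)))
  expect_equal(auc(s, lab), ref, tolerance = 1e-12)

  # null property: scores independent of labels
  set.seed(18)
  s2 <- rnorm(4000); lab2 <- sample(c("high", "low"), 4000, replace = TRUE)
  expect_lt(abs(auc(s2, lab2) - 0.5), 0.05)
  expect_warning(expect_true(is.na(auc(1:3, rep("high", 3)))), "single")
})

test_that("strong signal is learned and shuffled labels are not", {
  set.seed(23)
  n <- 80
  signal <- c(rnorm(n / 2, 0, 0.3), rnorm(n / 2, 5, 0.3))
  x <- data.frame(s = signal, junk = rnorm(n))
  labels <- rep(c("low", "high"), each = n / 2)
  for (alg in c("knn", "sgd")) {
    cv <- cross_validate(x, labels, classifier_spec(alg, cv_folds = 10))
    p <- confusion_partition(labels, cv$predicted)
    expect_gte(classification_accuracy(p), 0.9)
  }
  # with shuffled labels, accuracy settles near the majority proportion;
  # checked at n = 200 where the CV fold-imbalance bias is negligible
  n2 <- 200
  x2 <- data.frame(s = c(rnorm(n2 / 2, 0, 0.3), rnorm(n2 / 2, 5, 0.3)),
                   junk = rnorm(n2))
  labels2 <- rep(c("low", "high"), each = n2 / 2)
  for (alg in c("knn", "sgd")) {
    devs <- vapply(1:3, function(i) {
      shuffled <- sample(labels2)
      cv <- cross_validate(x2, shuffled, classifier_spec(alg,
                                                         cv_folds = 10))
      p <- confusion_partition(shuffled, cv$predicted)
      classification_accuracy(p) - max(table(shuffled)) / n2
    }, numeric(1))
    expect_lt(abs(mean(devs)), 0.1)
  }
})

test_that("classify_target reports both models and drops missing rows", {
  trial <- fixture_trial()
  clr <- fixture_clr()
  feats <- data.frame(dose = trial$records$dose, clr_Cu = clr$clr_Cu,
                      clr_P = clr$clr_P, clr_N = clr$clr_N)
  vals <- trial$records$yield
  vals[c(3, 10)] <- NA
  expect_message(
    res <- classify_target(feats, vals, target_spec("yield", 16),
                           cv_folds = 5, cv_seed = 1),
    "dropping 2 rows")
  expect_setequal(names(res$models), c("knn", "sgd"))
  expect_equal(res$models$knn$partition$n_total, 78)
  expect_true(res$best %in% c("knn", "sgd"))
  for (m in res$models) {
    expect_true(m$auc >= 0 && m$auc <= 1)
    expect_equal(m$partition$TN + m$partition$TP + m$partition$FN +
                   m$partition$FP, 78)
  }
})
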