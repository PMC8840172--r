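#' Target specification for cutoff classification
#'
#' A target variable is binarized at an agronomic cutoff. Orientation states
#' which side of the cutoff is the "high performance" class: for yield or
#' sweetness more is better (`high-is-good`), for titratable acidity less is
#' better (`low-is-good`). Values exactly at the cutoff map to the favorable
#' (`high`) class.
#'
#' @param name target identifier (a column of the trial records).
#' @param cutoff threshold in the target's own units.
#' @param orientation `"high-is-good"` or `"low-is-good"`.
#' @return list of class `target_spec`.
#' @export
target_spec <- function(name, cutoff,
                        orientation = c("high-is-good", "low-is-good")) {
  orientation <- match.arg(orientation)
  if (!is.finite(cutoff)) stop("cutoff must be finite")
  structure(list(name = name, cutoff = cutoff, orientation = orientation),
            class = "target_spec")
}

#' Binarize a target variable at its cutoff
#'
#' @param values numeric vector of target measurements (no missing values;
#'   drop incomplete rows upstream).
#' @param spec a [target_spec()].
#' @return character vector of labels `"high"` / `"low"`.
#' @export
binarize_target <- function(values, spec) {
  if (!inherits(spec, "target_spec")) stop("spec must be a target_spec")
  if (anyNA(values)) stop("missing values must be dropped before binarizing")
  high <- if (spec$orientation == "high-is-good") values >= spec$cutoff
  else values <= spec$cutoff
  ifelse(high, "high", "low")
}

#' Classifier specification
#'
#' Two families mirror a standard data-mining setup for small agronomic
#' tables: k-nearest neighbors on standardized features, and a
#' ridge-penalized logistic ("sgd") linear classifier.
#'
#' @param algorithm `"knn"` or `"sgd"`.
#' @param k neighbors for k-NN.
#' @param lambda L2 penalty for the linear classifier.
#' @param cv_folds stratified cross-validation folds (>= 2).
#' @param cv_seed seed fixing the fold assignment.
#' @return list of class `classifier_spec`.
#' @export
classifier_spec <- function(algorithm = c("knn", "sgd"), k = 5,
                            lambda = 0.01, cv_folds = 10, cv_seed = 1) {
  algorithm <- match.arg(algorithm)
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  structure(list(algorithm = algorithm, k = as.integer(k), lambda = lambda,
                 cv_folds = as.integer(cv_folds),
                 cv_seed = as.integer(cv_seed)),
            class = "classifier_spec")
}

# Stratified fold assignment keyed on specimen identifiers, so that row
# order never changes the folds: within each class, keys are sorted, then
# shuffled with the seeded RNG, then dealt round-robin.
.make_folds <- function(labels, k, seed, keys = seq_along(labels)) {
  n <- length(labels)
  min_class <- min(table(labels))
  if (min_class < k) {
    warning(sprintf(
      "smallest class has %d specimens; reducing folds from %d to %d",
      min_class, k, max(min_class, 2L)))
    k <- max(min_class, 2L)
  }
  fold <- integer(n)
  rng <- .seeded_sample(seed)
  for (cl in sort(unique(labels))) {
    idx <- which(labels == cl)
    idx <- idx[order(keys[idx])]
    idx <- idx[rng(length(idx))]
    fold[idx] <- rep_len(seq_len(k), length(idx))
  }
  list(fold = fold, k = k)
}

.seeded_sample <- function(seed) {
  function(n) {
    set.seed(seed + n)  # independent of call order across classes
    sample.int(n)
  }
}

#' Cross-validated out-of-fold classification
#'
#' Runs stratified k-fold cross-validation: features are standardized on
#' each training fold (zero mean, unit variance) and every specimen receives
#' exactly one out-of-fold predicted label and score (the predicted
#' probability of the `"high"` class).
#'
#' @param features data.frame or matrix of numeric features.
#' @param labels character vector of `"high"`/`"low"` actual labels.
#' @param spec a [classifier_spec()].
#' @param keys optional specimen identifiers fixing the fold assignment
#'   independently of row order.
#' @return object of class `cv_result`: list with `predicted`, `score`,
#'   `fold`, `labels`, `spec`.
#' @export
cross_validate <- function(features, labels, spec = classifier_spec(),
                           keys = seq_along(labels)) {
  x <- as.matrix(features)
  storage.mode(x) <- "double"
  n <- nrow(x)
  if (length(labels) != n) stop("labels must match feature rows")
  bad <- setdiff(unique(labels), c("high", "low"))
  if (length(bad)) stop("labels must be 'high'/'low'; found: ",
                        paste(bad, collapse = ", "))
  fd <- .make_folds(labels, spec$cv_folds, spec$cv_seed, keys)
  predicted <- character(n)
  score <- numeric(n)
  for (f in seq_len(fd$k)) {
    test <- which(fd$fold == f)
    train <- which(fd$fold != f)
    mu <- colMeans(x[train, , drop = FALSE])
    sdv <- apply(x[train, , drop = FALSE], 2, stats::sd)
    sdv[sdv == 0 | !is.finite(sdv)] <- 1
    xtr <- sweep(sweep(x[train, , drop = FALSE], 2, mu), 2, sdv, "/")
    xte <- sweep(sweep(x[test, , drop = FALSE], 2, mu), 2, sdv, "/")
    out <- .fit_predict(xtr, labels[train], xte, spec)
    predicted[test] <- out$label
    score[test] <- out$score
  }
  structure(list(predicted = predicted, score = score, fold = fd$fold,
                 labels = labels, spec = spec),
            class = "cv_result")
}

.fit_predict <- function(xtr, ytr, xte, spec) {
  if (all(apply(xtr, 2, stats::sd) == 0)) {
    # degenerate: no informative feature; fall back to the majority class
    maj <- names(which.max(table(ytr)))
    p <- mean(ytr == "high")
    return(list(label = rep(maj, nrow(xte)), score = rep(p, nrow(xte))))
  }
  if (spec$algorithm == "knn") {
    k <- min(spec$k, nrow(xtr))
    pred <- class::knn(xtr, xte, cl = factor(ytr), k = k, prob = TRUE)
    pwin <- attr(pred, "prob")
    score <- ifelse(pred == "high", pwin, 1 - pwin)
    list(label = as.character(pred), score = score)
  } else {
    fit <- suppressWarnings(
      glmnet::glmnet(xtr, factor(ytr, levels = c("low", "high")),
                     family = "binomial", alpha = 0,
                     lambda = spec$lambda, standardize = FALSE))
    score <- as.numeric(stats::predict(fit, xte, type = "response"))
    list(label = ifelse(score >= 0.5, "high", "low"), score = score)
  }
}

#' @export
print.cv_result <- function(x, ...) {
  p <- confusion_partition(x$labels, x$predicted)
  cat(sprintf("Cross-validated %s (%d folds): CA = %.3f, AUC = %.3f\n",
              x$spec$algorithm, max(x$fold),
              classification_accuracy(p),
              tryCatch(auc(x$score, x$labels), warning = function(w) NA)))
  invisible(x)
}

#' Confusion partition under the high/low performance convention
#'
#' Splits specimens into the four confusion-matrix cells with the
#' norm-population convention used in nutrient diagnosis: *true negatives*
#' are specimens both predicted and observed `high` (the high-performing,
#' nutritionally balanced population from which standards are derived),
#' *true positives* are predicted and observed `low`, *false negatives* are
#' predicted `high` but observed `low`, *false positives* predicted `low`
#' but observed `high`.
#'
#' @param actual,predicted character vectors of `"high"`/`"low"` labels.
#' @return list of class `confusion_partition` with counts `TN, TP, FN, FP`,
#'   per-cell row `index` sets, and `n_total`.
#' @export
confusion_partition <- function(actual, predicted) {
  if (length(actual) != length(predicted))
    stop("label vectors must have equal length")
  bad <- setdiff(unique(c(actual, predicted)), c("high", "low"))
  if (length(bad)) stop("labels must be 'high'/'low'; found: ",
                        paste(bad, collapse = ", "))
  idx <- list(TN = which(predicted == "high" & actual == "high"),
              TP = which(predicted == "low" & actual == "low"),
              FN = which(predicted == "high" & actual == "low"),
              FP = which(predicted == "low" & actual == "high"))
  structure(list(TN = length(idx$TN), TP = length(idx$TP),
                 FN = length(idx$FN), FP = length(idx$FP),
                 index = idx, n_total = length(actual)),
            class = "confusion_partition")
}

#' @export
print.confusion_partition <- function(x, ...) {
  cat(sprintf("Confusion partition (n = %d): TN=%d TP=%d FN=%d FP=%d, CA=%.3f\n",
              x$n_total, x$TN, x$TP, x$FN, x$FP,
              classification_accuracy(x)))
  invisible(x)
}

#' Classification accuracy
#'
#' `(TN + TP) / n_total`.
#'
#' @param p a [confusion_partition()], or a list with `TN`, `TP`, `FN`, `FP`
#'   counts.
#' @return fraction in \[0, 1\].
#' @export
#' @examples
#' classification_accuracy(list(TN = 58, TP = 20, FN = 2, FP = 0))  # 0.975
classification_accuracy <- function(p) {
  n <- if (!is.null(p$n_total)) p$n_total else p$TN + p$TP + p$FN + p$FP
  if (n == 0) stop("empty partition: accuracy undefined")
  (p$TN + p$TP) / n
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of scores for separating the `"high"`
#' class from the `"low"` class; tied scores contribute 1/2.
#'
#' @param scores numeric scores, larger meaning more `"high"`-like.
#' @param actual character labels `"high"`/`"low"`.
#' @return AUC in \[0, 1\], or `NA` with a warning if only one class is
#'   present.
#' @export
auc <- function(scores, actual) {
  pos <- actual == "high"
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) {
    warning("AUC undefined with a single class; returning NA")
    return(NA_real_)
  }
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Run both classifier families on one target
#'
#' Binarizes the target, cross-validates k-NN and the linear classifier with
#' a shared fold seed, and reports each model's AUC, classification accuracy
#' and confusion partition, flagging the better model by AUC.
#'
#' @param features numeric feature table.
#' @param values numeric target measurements (rows with `NA` are dropped,
#'   with a message).
#' @param spec a [target_spec()].
#' @param cv_folds,cv_seed cross-validation control shared by both models.
#' @param keys optional specimen keys (recycled to kept rows).
#' @return list of class `target_classification` with per-model results and
#'   `best` (name of the higher-AUC model).
#' @export
classify_target <- function(features, values, spec, cv_folds = 10,
                            cv_seed = 1, keys = seq_along(values)) {
  keep <- !is.na(values)
  if (!all(keep))
    message(sprintf("[classify] %s: dropping %d rows with missing target",
                    spec$name, sum(!keep)))
  x <- as.data.frame(features)[keep, , drop = FALSE]
  v <- values[keep]
  keys <- keys[keep]
  labels <- binarize_target(v, spec)
  models <- lapply(c(knn = "knn", sgd = "sgd"), function(alg) {
    cv <- cross_validate(x, labels,
                         classifier_spec(alg, cv_folds = cv_folds,
                                         cv_seed = cv_seed),
                         keys = keys)
    part <- confusion_partition(labels, cv$predicted)
    list(cv = cv, partition = part,
         ca = classification_accuracy(part),
         auc = suppressWarnings(auc(cv$score, labels)))
  })
  aucs <- vapply(models, `[[`, numeric(1), "auc")
  structure(list(target = spec$name, cutoff = spec$cutoff,
                 orientation = spec$orientation, labels = labels,
                 kept = which(keep), models = models,
                 best = names(models)[which.max(aucs)]),
            class = "target_classification")
}

#' @export
print.target_classification <- function(x, ...) {
  cat(sprintf("Target '%s' (cutoff %g, %s)\n", x$target, x$cutoff,
              x$orientation))
  for (m in names(x$models)) {
    r <- x$models[[m]]
    cat(sprintf("  %s%s: AUC %.3f, CA %.3f (TN=%d TP=%d FN=%d FP=%d)\n",
                m, if (m == x$best) " *" else "  ", r$auc, r$ca,
                r$partition$TN, r$partition$TP, r$partition$FN,
                r$partition$FP))
  }
  invisible(x)
}
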