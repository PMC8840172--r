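#' Univariate regression feature ranking
#'
#' Scores each feature by the F statistic of the simple linear regression of
#' the target on that (standardized) feature, `F = (n - 2) r^2 / (1 - r^2)`.
#' Perfectly collinear features receive a capped sentinel score; constant
#' features score zero with a warning.
#'
#' @param features data.frame or matrix of numeric features.
#' @param target numeric target series.
#' @param cap sentinel value reported when `r^2` is numerically 1.
#' @return data.frame `feature, r, score`, ordered as given.
#' @export
univariate_rank <- function(features, target, cap = 1e6) {
  x <- as.matrix(features)
  n <- nrow(x)
  if (n < 3) stop("at least 3 observations are needed")
  if (length(target) != n) stop("target must match feature rows")
  if (stats::sd(target) == 0) {
    warning("constant target: all scores are 0")
    return(data.frame(feature = colnames(x), r = 0, score = 0))
  }
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) warning("constant features score 0: ",
                             paste(colnames(x)[sds == 0], collapse = ", "))
  r <- rep(0, ncol(x))
  r[sds > 0] <- suppressWarnings(
    as.numeric(stats::cor(x[, sds > 0, drop = FALSE], target)))
  r2 <- r^2
  score <- ifelse(1 - r2 < 1e-12, cap, (n - 2) * r2 / (1 - r2))
  data.frame(feature = colnames(x), r = r, score = score)
}

#' Feature-ranking table over several targets
#'
#' @param features numeric feature table.
#' @param targets data.frame of target series (one column per target).
#' @return data.frame of F scores, rows = targets, columns = features.
#' @export
univariate_rank_table <- function(features, targets) {
  targets <- as.data.frame(targets)
  rows <- lapply(names(targets), function(tg) {
    ok <- !is.na(targets[[tg]])
    rk <- univariate_rank(as.data.frame(features)[ok, , drop = FALSE],
                          targets[[tg]][ok])
    stats::setNames(rk$score, rk$feature)
  })
  out <- as.data.frame(do.call(rbind, rows))
  rownames(out) <- names(targets)
  out
}

#' Per-season dose-response trend analysis
#'
#' For each season, a randomized-complete-block ANOVA of the response on
#' block and N dose, with orthogonal polynomial contrasts splitting the dose
#' effect into linear and quadratic trends (tested at the 5% level). The
#' coefficient of variation is `100 * sqrt(residual MS) / grand mean`, and
#' the dose with the highest observed mean response is reported.
#'
#' @param records data.frame with columns `year`, `dose`, `block` and the
#'   response.
#' @param response name of the response column (default `"yield"`).
#' @return object of class `dose_trend`: data.frame with one row per season
#'   (`year, p_linear, p_quadratic, linear_sig, quadratic_sig, cv_percent,
#'   dose_max`).
#' @export
dose_trend <- function(records, response = "yield") {
  records <- as.data.frame(records)
  need <- c("year", "dose", "block", response)
  if (!all(need %in% names(records)))
    stop("records must have columns: ", paste(need, collapse = ", "))
  out <- lapply(sort(unique(records$year)), function(yr) {
    d <- records[records$year == yr, ]
    tab <- table(d$dose)
    if (any(tab == 0) || length(tab) < 3)
      stop("every dose level needs observations in season ", yr)
    dose_f <- ordered(d$dose)
    block_f <- factor(d$block)
    fit <- stats::aov(d[[response]] ~ block_f + dose_f)
    sm <- summary(fit, split = list(dose_f = list(linear = 1, quadratic = 2)))
    tabsm <- sm[[1]]
    rn <- trimws(rownames(tabsm))
    p_lin <- tabsm[grep("linear", rn), "Pr(>F)"][1]
    p_quad <- tabsm[grep("quadratic", rn), "Pr(>F)"][1]
    mse <- tabsm[grep("^Residuals", rn), "Mean Sq"][1]
    means <- tapply(d[[response]], d$dose, mean)
    data.frame(year = yr,
               p_linear = p_lin, p_quadratic = p_quad,
               linear_sig = !is.na(p_lin) && p_lin < 0.05,
               quadratic_sig = !is.na(p_quad) && p_quad < 0.05,
               cv_percent = 100 * sqrt(mse) / mean(d[[response]]),
               dose_max = dose_of_maximum(as.numeric(names(means)), means))
  })
  structure(do.call(rbind, out), class = c("dose_trend", "data.frame"),
            response = response)
}

#' Dose with the maximum observed mean response
#'
#' @param dose numeric dose levels.
#' @param value mean response at each level.
#' @return the dose at which `value` is largest.
#' @export
#' @examples
#' dose_of_maximum(c(0, 40, 80, 120, 160), c(20.7, 26.0, 35.4, 28.1, 24.3))
dose_of_maximum <- function(dose, value) {
  if (length(dose) != length(value)) stop("dose and value lengths differ")
  dose[which.max(value)]
}

#' @export
print.dose_trend <- function(x, ...) {
  cat(sprintf("Dose-response trends for '%s' (RCB ANOVA, polynomial contrasts)\n",
              attr(x, "response")))
  df <- data.frame(year = x$year,
                   trend = ifelse(x$quadratic_sig, "Q *",
                                  ifelse(x$linear_sig, "L *", "ns")),
                   `CV %` = round(x$cv_percent, 1),
                   `dose of max` = x$dose_max, check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Variance partition across design factors
#'
#' Main-effects ANOVA (season, dose, block as factors) expressed as each
#' factor's share of the total sum of squares, plus the residual share.
#' Shares sum to 1.
#'
#' @param records data.frame with `year`, `dose`, `block` and the response.
#' @param response response column name.
#' @return object of class `variance_partition`: named numeric vector
#'   `season, dose, block, residual`.
#' @export
variance_partition <- function(records, response = "yield") {
  records <- as.data.frame(records)
  if (length(unique(records$year)) < 2)
    stop("variance partition needs at least 2 seasons")
  fit <- stats::aov(records[[response]] ~ factor(records$year) +
                      factor(records$dose) + factor(records$block))
  tab <- summary(fit)[[1]]
  ss <- tab[, "Sum Sq"]
  shares <- ss / sum(ss)
  names(shares) <- c("season", "dose", "block", "residual")
  structure(shares, class = "variance_partition", response = response)
}

#' @export
print.variance_partition <- function(x, ...) {
  cat(sprintf("Variance partition for '%s' (share of total SS)\n",
              attr(x, "response")))
  v <- unclass(x)
  attributes(v) <- list(names = names(x))
  print(round(v, 3))
  invisible(x)
}

#' Season-carryover prediction (gradient boosting)
#'
#' Predicts each plot's target in a test season from its *previous* season's
#' foliar clr composition and target (the stored-nutrient and carbohydrate
#' proxies) together with the current season's fertilization. The learner is
#' gradient boosting (200 trees, depth 3, learning rate 0.1) with a fixed
#' seed; set `use_prior_target = FALSE` for a no-carryover baseline.
#'
#' @param trial a `peach_trial` from [simulate_trial()], or a list with
#'   `records`, `foliar`, `baseline` of the same shape.
#' @param response target column (default `"yield"`).
#' @param test_year season held out for prediction (default: last season).
#' @param use_prior_target include the previous-season target as a feature.
#' @param cutoff optional performance cutoff: when given, the fraction of
#'   test predictions at or above it is reported as `p_high`.
#' @param nrounds,max_depth,eta gradient-boosting hyperparameters.
#' @param seed seed for the learner.
#' @return object of class `carryover_fit`: list with `predictions`
#'   (per test record: `plot, dose, actual, predicted`), `dose_curve`
#'   (per-dose mean predicted response), `rmse`, `p_high`, `n_train`,
#'   `n_test`.
#' @export
carryover_fit_predict <- function(trial, response = "yield",
                                  test_year = NULL,
                                  use_prior_target = TRUE,
                                  cutoff = NULL,
                                  nrounds = 200, max_depth = 3, eta = 0.1,
                                  seed = 1) {
  rec <- trial$records
  years <- sort(unique(rec$year))
  if (is.null(test_year)) test_year <- years[length(years)]
  if (!test_year %in% years) stop("test_year not present in the records")

  clr <- as.matrix(clr_transform(trial$foliar))
  base_clr <- as.matrix(clr_transform(trial$baseline$foliar))
  base_rec <- trial$baseline$records

  prior_feats <- function(rows) {
    yr <- rec$year[rows][1]
    if (yr == years[1]) {
      m <- match(rec$plot[rows], base_rec$plot)
      if (anyNA(m))
        stop("missing prior-season linkage for plots: ",
             paste(rec$plot[rows][is.na(m)], collapse = ", "))
      list(clr = base_clr[m, , drop = FALSE],
           target = base_rec[[response]][m])
    } else {
      prev <- which(rec$year == yr - 1L)
      m <- match(rec$plot[rows], rec$plot[prev])
      if (anyNA(m))
        stop("missing prior-season linkage for plots: ",
             paste(rec$plot[rows][is.na(m)], collapse = ", "))
      list(clr = clr[prev[m], , drop = FALSE],
           target = rec[[response]][prev[m]])
    }
  }
  build <- function(rows) {
    pf <- prior_feats(rows)
    x <- cbind(pf$clr, fertilization = rec$dose[rows])
    if (use_prior_target) x <- cbind(x, prior_target = pf$target)
    x
  }
  train_rows <- which(rec$year != test_year & rec$year < test_year)
  test_rows <- which(rec$year == test_year)
  xtr <- do.call(rbind, lapply(split(train_rows, rec$year[train_rows]), build))
  ytr <- unlist(lapply(split(train_rows, rec$year[train_rows]),
                       function(r) rec[[response]][r]), use.names = FALSE)
  xte <- build(test_rows)

  booster <- xgboost::xgboost(xtr, ytr, nrounds = nrounds,
                              max_depth = max_depth, learning_rate = eta,
                              objective = "reg:squarederror",
                              nthreads = 1, verbosity = 0, seed = seed)
  pred <- stats::predict(booster, xte)
  actual <- rec[[response]][test_rows]
  predictions <- data.frame(plot = rec$plot[test_rows],
                            dose = rec$dose[test_rows],
                            actual = actual, predicted = pred)
  dose_curve <- stats::aggregate(predicted ~ dose, data = predictions, mean)
  structure(list(predictions = predictions, dose_curve = dose_curve,
                 rmse = sqrt(mean((pred - actual)^2)),
                 p_high = if (is.null(cutoff)) NA_real_ else
                   mean(pred >= cutoff),
                 n_train = nrow(xtr), n_test = nrow(xte),
                 test_year = test_year, response = response,
                 use_prior_target = use_prior_target),
            class = "carryover_fit")
}

#' @export
print.carryover_fit <- function(x, ...) {
  cat(sprintf("Carryover prediction of '%s' for season %s\n", x$response,
              x$test_year))
  cat(sprintf("  trained on %d records, tested on %d; RMSE %.2f\n",
              x$n_train, x$n_test, x$rmse))
  if (is.finite(x$p_high))
    cat(sprintf("  predicted high-performance fraction: %.2f\n", x$p_high))
  cat("  predicted dose curve:\n")
  print(x$dose_curve, row.names = FALSE)
  invisible(x)
}
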