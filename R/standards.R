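#' Select the true-negative (norm population) rows
#'
#' Nutrient standards are derived from the specimens both predicted and
#' observed to be high-performing: the true negatives of the confusion
#' partition.
#'
#' @param partition a [confusion_partition()] whose index sets reference
#'   rows of `clr_table`.
#' @param clr_table data.frame of clr values (one row per specimen).
#' @return the TN-indexed rows of `clr_table`.
#' @export
select_true_negatives <- function(partition, clr_table) {
  stopifnot(inherits(partition, "confusion_partition"))
  if (partition$n_total != nrow(clr_table))
    stop("partition and clr table describe different numbers of specimens")
  if (!length(partition$index$TN))
    stop("no true-negative specimens: no standards can be derived")
  clr_table[partition$index$TN, , drop = FALSE]
}

#' Foliar nutrient standards on the clr scale
#'
#' Per-component arithmetic mean and sample standard deviation of the clr
#' values of the norm (true-negative) population. Because every clr row sums
#' to zero, the component means do as well.
#'
#' @param tn_table data.frame of clr values for the true-negative specimens
#'   (columns `clr_*` or bare component names, order
#'   [nutrient_components()]).
#' @return object of class `nutrient_standards`: data.frame with
#'   `component`, `clr_mean`, `clr_sd`, and attribute `n`.
#' @export
clr_standards <- function(tn_table) {
  x <- as.matrix(tn_table)
  if (nrow(x) < 2) stop("at least 2 specimens are needed to estimate an SD")
  if (ncol(x) != length(.parts))
    stop("expected ", length(.parts), " clr components")
  out <- data.frame(component = .parts,
                    clr_mean = colMeans(x),
                    clr_sd = apply(x, 2, stats::sd),
                    row.names = NULL)
  structure(out, class = c("nutrient_standards", "data.frame"),
            n = nrow(x))
}

#' @export
print.nutrient_standards <- function(x, digits = 3, ...) {
  cat(sprintf("Foliar nutrient standards (clr scale), n = %d specimens\n",
              attr(x, "n")))
  df <- data.frame(component = x$component,
                   `clr mean` = round(x$clr_mean, digits),
                   `clr sd` = round(x$clr_sd, digits),
                   check.names = FALSE)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Back-transformed concentration ranges from clr standards
#'
#' Two estimation modes are provided because a single parametric rule cannot
#' describe every published norm table:
#' \describe{
#'   \item{parametric-ci}{per component, the clr confidence bounds
#'     `clr_mean +/- t(1 - alpha/2, n - 1) * clr_sd / sqrt(n)` are
#'     exponentiated with all *other* components held at `exp(clr_mean)`,
#'     then closed to the measurement unit.}
#'   \item{empirical-quantile}{bounds are the `alpha/2` and `1 - alpha/2`
#'     quantiles of the per-specimen closed concentrations.}
#' }
#' Macronutrients and the filling value are reported in g/kg, micronutrients
#' in mg/kg.
#'
#' @param standards a [clr_standards()] object.
#' @param alpha two-tailed significance level (default 0.01).
#' @param mode `"parametric-ci"` or `"empirical-quantile"`.
#' @param tn_table the TN clr table (required for the empirical mode).
#' @param unit_total closure unit in g/kg.
#' @return data.frame `component, conc_low, conc_high, unit`.
#' @export
concentration_ranges <- function(standards, alpha = 0.01,
                                 mode = c("parametric-ci",
                                          "empirical-quantile"),
                                 tn_table = NULL, unit_total = 1000) {
  mode <- match.arg(mode)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  stopifnot(inherits(standards, "nutrient_standards"))
  n <- attr(standards, "n")
  mu <- standards$clr_mean
  if (mode == "parametric-ci") {
    if (n < 2) stop("parametric mode needs n >= 2")
    half <- stats::qt(1 - alpha / 2, df = n - 1) * standards$clr_sd / sqrt(n)
    lo <- hi <- numeric(length(mu))
    for (i in seq_along(mu)) {
      v_lo <- v_hi <- mu
      v_lo[i] <- mu[i] - half[i]
      v_hi[i] <- mu[i] + half[i]
      lo[i] <- exp(v_lo[i]) / sum(exp(v_lo)) * unit_total
      hi[i] <- exp(v_hi[i]) / sum(exp(v_hi)) * unit_total
    }
  } else {
    if (is.null(tn_table))
      stop("empirical-quantile mode needs the TN clr table")
    conc <- as.matrix(clr_inverse(as.matrix(tn_table),
                                  unit_total = unit_total))
    conc[, .micros] <- conc[, .micros] / 1000  # back to g/kg for quantiles
    lo <- apply(conc, 2, stats::quantile, probs = alpha / 2, names = FALSE)
    hi <- apply(conc, 2, stats::quantile, probs = 1 - alpha / 2,
                names = FALSE)
  }
  is_micro <- standards$component %in% .micros
  scale <- ifelse(is_micro, 1000, 1)  # report micros in mg/kg
  data.frame(component = standards$component,
             conc_low = lo * scale, conc_high = hi * scale,
             unit = ifelse(is_micro, "mg/kg", "g/kg"))
}

#' Sufficiency range as a highest-density interval
#'
#' Estimates the concentration interval holding a given fraction (default
#' 90%) of the density mass of a nutrient among high-performing specimens,
#' using a Gaussian kernel with Silverman's rule-of-thumb bandwidth. For a
#' symmetric unimodal sample this coincides with the central quantile
#' interval up to estimation error.
#'
#' @param values numeric concentration series (>= 30 values).
#' @param coverage fraction of density mass to cover, in (0, 1).
#' @return object of class `sufficiency_range`: list with `low`, `high`,
#'   `coverage`.
#' @export
sufficiency_range_density <- function(values, coverage = 0.90) {
  if (coverage <= 0 || coverage >= 1) stop("coverage must be in (0, 1)")
  values <- values[!is.na(values)]
  if (length(values) < 30)
    stop("at least 30 values are needed for a density-based range")
  if (stats::sd(values) == 0)
    return(structure(list(low = values[1], high = values[1],
                          coverage = coverage),
                     class = "sufficiency_range"))
  d <- stats::density(values, bw = "nrd0", n = 4096)
  dx <- d$x[2] - d$x[1]
  ord <- order(d$y, decreasing = TRUE)
  mass <- cumsum(d$y[ord]) * dx
  m <- which(mass >= coverage)[1]
  if (is.na(m)) m <- length(ord)
  sel <- ord[seq_len(m)]
  structure(list(low = min(d$x[sel]), high = max(d$x[sel]),
                 coverage = coverage),
            class = "sufficiency_range")
}

#' @export
print.sufficiency_range <- function(x, ...) {
  cat(sprintf("Sufficiency range (%.0f%% highest density): %.2f to %.2f\n",
              100 * x$coverage, x$low, x$high))
  invisible(x)
}

#' Critical value by linear-plateau (segmented) regression
#'
#' Fits the agronomic linear-plateau response: the target changes linearly
#' in the predictor up to a breakpoint and is constant beyond it (or,
#' mirrored, is constant up to the breakpoint and linear after). The
#' breakpoint — the critical value — is located by grid search over the
#' observed predictor values and their midpoints, minimizing the residual
#' sum of squares of the per-candidate least-squares fit; the two
#' orientations compete by SSE. A case-resampling bootstrap provides a
#' percentile confidence interval.
#'
#' @param x predictor series (e.g., a clr component), >= 10 points.
#' @param y response series (target units).
#' @param n_boot bootstrap resamples for the CI (0 to skip).
#' @param seed seed for the bootstrap.
#' @param level CI level.
#' @return object of class `linear_plateau` with elements `breakpoint`,
#'   `form` (`"trend-plateau"` or `"plateau-trend"`), `coefficients`
#'   (`intercept`, `slope`), `plateau_level`, `sse`, `ci`, `fitted`,
#'   `residuals`, `x`, `y`.
#' @export
critical_value_piecewise <- function(x, y, n_boot = 200, seed = 1,
                                     level = 0.95) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 10) stop("at least 10 points are needed")
  if (stats::var(y) < 1e-12)
    stop("response is flat: breakpoint indeterminate")
  fit <- .lp_fit(x, y)
  ci <- c(NA_real_, NA_real_)
  boot_bp <- NULL
  if (n_boot > 0) {
    set.seed(seed)
    n <- length(x)
    boot_bp <- vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, replace = TRUE)
      tryCatch(.lp_fit(x[idx], y[idx])$breakpoint,
               error = function(e) NA_real_)
    }, numeric(1))
    probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
    ci <- stats::quantile(boot_bp, probs = probs, na.rm = TRUE,
                          names = FALSE)
  }
  structure(c(fit, list(ci = ci, level = level, boot = boot_bp,
                        x = x, y = y)),
            class = "linear_plateau")
}

# Grid-search least squares for both piecewise orientations:
#   trend-plateau:  y = a + b * min(x, bp)
#   plateau-trend:  y = a + b * max(x, bp)
# The SSE profile over candidate breakpoints is evaluated in O(1) per
# candidate from prefix sums over the sorted predictor, which keeps the
# case bootstrap cheap. Candidates are the observed values and their
# midpoints (interior only).
.lp_fit <- function(x, y) {
  ord <- order(x)
  xs <- x[ord]; ys <- y[ord]
  n <- length(xs)
  ux <- unique(xs)
  if (length(ux) < 3) stop("predictor must take at least 3 distinct values")
  cand <- sort(unique(c(ux, (ux[-1] + ux[-length(ux)]) / 2)))
  cand <- cand[cand > ux[1] & cand < ux[length(ux)]]
  Px <- c(0, cumsum(xs)); Pxx <- c(0, cumsum(xs^2))
  Py <- c(0, cumsum(ys)); Pxy <- c(0, cumsum(xs * ys))
  Sx <- Px[n + 1]; Sxx <- Pxx[n + 1]
  Sy <- Py[n + 1]; Sxy <- Pxy[n + 1]
  Syy_c <- sum(ys^2) - Sy^2 / n
  k <- findInterval(cand, xs)          # count of x <= candidate
  sse_of <- function(Sz, Szz, Szy) {
    Szz_c <- Szz - Sz^2 / n
    Szy_c <- Szy - Sz * Sy / n
    sse <- Syy_c - ifelse(Szz_c > 1e-12, Szy_c^2 / Szz_c, -Inf)
    pmax(sse, 0)
  }
  # trend-plateau: z = pmin(x, bp)
  SzA <- Px[k + 1] + cand * (n - k)
  SzzA <- Pxx[k + 1] + cand^2 * (n - k)
  SzyA <- Pxy[k + 1] + cand * (Sy - Py[k + 1])
  sseA <- sse_of(SzA, SzzA, SzyA)
  # plateau-trend: z = pmax(x, bp)
  SzB <- cand * k + (Sx - Px[k + 1])
  SzzB <- cand^2 * k + (Sxx - Pxx[k + 1])
  SzyB <- cand * Py[k + 1] + (Sxy - Pxy[k + 1])
  sseB <- sse_of(SzB, SzzB, SzyB)
  if (min(sseA) <= min(sseB)) {
    form <- "trend-plateau"; i <- which.min(sseA)
    Sz <- SzA[i]; Szz <- SzzA[i]; Szy <- SzyA[i]; sse <- sseA[i]
  } else {
    form <- "plateau-trend"; i <- which.min(sseB)
    Sz <- SzB[i]; Szz <- SzzB[i]; Szy <- SzyB[i]; sse <- sseB[i]
  }
  bp <- cand[i]
  b <- (Szy - Sz * Sy / n) / (Szz - Sz^2 / n)
  a <- (Sy - b * Sz) / n
  z <- if (form == "trend-plateau") pmin(x, bp) else pmax(x, bp)
  fitted <- a + b * z
  list(breakpoint = bp, form = form,
       coefficients = c(intercept = a, slope = b),
       sse = sse, fitted = fitted, residuals = y - fitted,
       plateau_level = a + b * bp)
}

#' @export
print.linear_plateau <- function(x, ...) {
  cat(sprintf("Linear-plateau fit (%s)\n", x$form))
  cat(sprintf("  critical value (breakpoint): %.4f", x$breakpoint))
  if (all(is.finite(x$ci)))
    cat(sprintf("  [%.4f, %.4f] %.0f%% bootstrap CI",
                x$ci[1], x$ci[2], 100 * x$level))
  cat("\n")
  cat(sprintf("  slope %.4f, plateau level %.4f, SSE %.4g\n",
              x$coefficients[["slope"]], x$plateau_level, x$sse))
  invisible(x)
}

#' @export
coef.linear_plateau <- function(object, ...) {
  c(object$coefficients, breakpoint = object$breakpoint)
}

#' @export
predict.linear_plateau <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$x else
    if (is.list(newdata)) newdata$x else newdata
  z <- if (object$form == "trend-plateau") pmin(x, object$breakpoint)
  else pmax(x, object$breakpoint)
  object$coefficients[["intercept"]] + object$coefficients[["slope"]] * z
}

#' @export
residuals.linear_plateau <- function(object, ...) object$residuals

#' @export
fitted.linear_plateau <- function(object, ...) object$fitted

#' @export
confint.linear_plateau <- function(object, parm = "breakpoint",
                                   level = NULL, ...) {
  if (!is.null(level) && !isTRUE(all.equal(level, object$level)))
    warning("CI level is fixed at fit time; returning the stored interval")
  matrix(object$ci, nrow = 1,
         dimnames = list("breakpoint",
                         sprintf("%.1f %%", 100 * c((1 - object$level) / 2,
                                                    1 - (1 - object$level) / 2))))
}

#' @export
plot.linear_plateau <- function(x, ...) {
  ord <- order(x$x)
  graphics::plot(x$x, x$y, xlab = "predictor", ylab = "response",
                 main = sprintf("Linear-plateau fit (critical value %.3f)",
                                x$breakpoint), ...)
  graphics::lines(x$x[ord], x$fitted[ord], lwd = 2)
  graphics::abline(v = x$breakpoint, lty = 2)
  invisible(x)
}

#' Simple linear effect of a clr component on a target
#'
#' Ordinary least squares of the target on one predictor, with the Pearson
#' correlation, for linear (non-plateau) responses such as titratable
#' acidity on clr_P.
#'
#' @param x predictor series (>= 3 points, not constant).
#' @param y response series.
#' @return list with `slope`, `intercept`, `r`, and the underlying `lm` fit.
#' @export
linear_effect <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3) stop("at least 3 points are needed")
  if (stats::sd(x) == 0) stop("predictor is constant")
  fit <- stats::lm(y ~ x)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = stats::cor(x, y), fit = fit)
}
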