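test_that("true negatives are selected by partition index", {
  clr <- data.frame(matrix(rnorm(44), nrow = 4,
                           dimnames = list(NULL, paste0("clr_",
                                                        nutrient_components()))))
  part <- confusion_partition(c("high", "low", "high", "low"),
                              c("high", "low", "low", "high"))
  tn <- select_true_negatives(part, clr)
  expect_equal(nrow(tn), 1)
  expect_equal(tn, clr[1, ], ignore_attr = TRUE)

  all_tn <- confusion_partition(rep("high", 4), rep("high", 4))
  expect_equal(nrow(select_true_negatives(all_tn, clr)), 4)

  none <- confusion_partition(rep("low", 4), rep("low", 4))
  expect_error(select_true_negatives(none, clr), "no standards")
})

test_that("clr standards are means and n-1 SDs that stay on the simplex", {
  two <- as.data.frame(matrix(rep(rnorm(11), 2), nrow = 2, byrow = TRUE))
  two <- two - rowMeans(two)
  std <- clr_standards(two)
  expect_equal(std$clr_sd, rep(0, 11))
  expect_equal(sum(std$clr_mean), 0, tolerance = 1e-9)
  expect_error(clr_standards(two[1, ]), "at least 2")

  # sampling recovery: standards of a large TN sample drawn around the
  # reference norms recover the location within 3 standard errors
  truth <- ground_truth()
  set.seed(404)
  n <- 5000
  z <- matrix(rnorm(n * 11, mean = rep(truth$clr_location, each = n),
                    sd = rep(truth$clr_spread, each = n)), nrow = n)
  z <- z - rowMeans(z)
  std_big <- clr_standards(as.data.frame(z))
  se <- std_big$clr_sd / sqrt(n)
  expect_true(all(abs(std_big$clr_mean - truth$clr_location) <= 3 * se))
  expect_equal(sum(std_big$clr_mean), 0, tolerance = 1e-9)
})

test_that("parametric concentration ranges match the closed-form oracle", {
  # degenerate 2-part check via an 11-part composition with known means:
  # bounds computed by hand with the exp/closure arithmetic
  mu <- ground_truth()$clr_location
  sdv <- ground_truth()$clr_spread
  n <- 58
  set.seed(12)
  z <- matrix(rnorm(300 * 11, rep(mu, each = 300), rep(sdv, each = 300)),
              nrow = 300)
  z <- z - rowMeans(z)
  std <- clr_standards(as.data.frame(z))
  rng <- concentration_ranges(std, alpha = 0.01)
  # oracle: exponentiate the CI bound for component i, others at exp(mean)
  i <- 1  # N
  half <- qt(0.995, nrow(z) - 1) * std$clr_sd[i] / sqrt(nrow(z))
  vlo <- std$clr_mean; vlo[i] <- vlo[i] - half
  expect_equal(rng$conc_low[i], exp(vlo[i]) / sum(exp(vlo)) * 1000,
               tolerance = 1e-12)
  expect_true(all(rng$conc_low <= rng$conc_high))
  expect_equal(rng$unit, rep(c("g/kg", "mg/kg", "g/kg"), c(5, 5, 1)))

  # zero spread collapses the range onto the closed mean concentration
  z0 <- as.data.frame(matrix(rep(mu, 3), nrow = 3, byrow = TRUE))
  std0 <- clr_standards(z0)
  rng0 <- concentration_ranges(std0, alpha = 0.01)
  expect_equal(rng0$conc_low, rng0$conc_high, tolerance = 1e-9)
  closed <- exp(mu) / sum(exp(mu)) * 1000
  expect_equal(rng0$conc_low[1], closed[[1]], tolerance = 1e-9)

  # closed mean concentrations sum to the measurement unit exactly
  expect_equal(sum(closed), 1000, tolerance = 1e-9)

  # range width shrinks with n at fixed SD
  widths <- vapply(c(10, 100, 1000), function(nn) {
    attr(std, "n") <- nn
    r <- concentration_ranges(std, alpha = 0.01)
    r$conc_high[1] - r$conc_low[1]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))

  expect_error(concentration_ranges(std, alpha = 1.2), "alpha")
  # empirical mode needs the TN table and brackets the parametric CI
  expect_error(concentration_ranges(std, mode = "empirical-quantile"),
               "TN clr table")
  rng_e <- concentration_ranges(std, mode = "empirical-quantile",
                                tn_table = z)
  expect_true(all(rng_e$conc_low < rng_e$conc_high))
  expect_true(all(rng_e$conc_low <= rng$conc_low + 1e-9))
})

test_that("highest-density sufficiency ranges behave like central
          intervals for symmetric samples", {
  set.seed(100)
  vals <- rnorm(10000, 27.95, 0.8815)
  sr <- sufficiency_range_density(vals, coverage = 0.90)
  qs <- quantile(vals, c(0.05, 0.95))
  expect_lt(abs(sr$low - qs[[1]]), 0.25)
  expect_lt(abs(sr$high - qs[[2]]), 0.25)

  # uniform sample: a 90% interval of a Uniform(0,1) has length ~0.9
  set.seed(101)
  u <- runif(10000)
  sru <- sufficiency_range_density(u, coverage = 0.90)
  expect_lt(abs((sru$high - sru$low) - 0.90), 0.05)

  const <- rep(5, 50)
  src <- sufficiency_range_density(const)
  expect_equal(c(src$low, src$high), c(5, 5))
  expect_error(sufficiency_range_density(rnorm(10)), "at least 30")
  expect_error(sufficiency_range_density(vals, coverage = 1), "coverage")
})

test_that("linear-plateau fits recover noise-free breakpoints exactly", {
  cases <- list(list(bp = -5.410, form = "trend-plateau"),
                list(bp = 0.556, form = "plateau-trend"),
                list(bp = 2.0, form = "trend-plateau"))
  for (cs in cases) {
    d <- make_plateau_data(cs$bp, cs$form)
    fit <- critical_value_piecewise(d$x, d$y, n_boot = 0)
    expect_equal(fit$breakpoint, cs$bp, tolerance = 1e-9)
    expect_equal(fit$form, cs$form)
    expect_lt(fit$sse, 1e-9)
  }
  # falling-then-plateau (acidity-style) is the same form, negative slope
  d <- make_plateau_data(1.0, "trend-plateau", slope = -3)
  fit <- critical_value_piecewise(d$x, d$y, n_boot = 0)
  expect_equal(fit$breakpoint, 1.0, tolerance = 1e-9)
  expect_lt(fit$coefficients[["slope"]], 0)
})

test_that("the breakpoint estimator is shift equivariant and guarded", {
  set.seed(55)
  x <- runif(60, -2, 2)
  y <- 4 + 2 * pmin(x, 0.3) + rnorm(60, 0, 0.2)
  f0 <- critical_value_piecewise(x, y, n_boot = 0)
  f1 <- critical_value_piecewise(x + 10, y, n_boot = 0)
  expect_equal(f1$breakpoint, f0$breakpoint + 10, tolerance = 1e-9)
  expect_error(critical_value_piecewise(x, rep(1, 60), n_boot = 0), "flat")
  expect_error(critical_value_piecewise(x[1:5], y[1:5], n_boot = 0),
               "at least 10")
})

test_that("bootstrap intervals usually cover the true breakpoint under
          noise", {
  true_bp <- -5.410
  plateau <- 10
  covered <- 0L
  n_rep <- 100
  for (r in seq_len(n_rep)) {
    set.seed(700 + r)
    x <- runif(200, true_bp - 1, true_bp + 1)
    y <- ifelse(x < true_bp, plateau + 5 * (x - true_bp), plateau) +
      rnorm(200, 0, 0.1 * plateau)  # noise sd at 10% of the plateau
    fit <- critical_value_piecewise(x, y, n_boot = 100, seed = r)
    if (fit$ci[1] <= true_bp && true_bp <= fit$ci[2])
      covered <- covered + 1L
  }
  expect_gte(covered / n_rep, 0.9)
})

test_that("linear effects recover slopes and correlations", {
  x <- seq(0, 5, by = 0.5)
  fit <- linear_effect(x, 2 - 0.5 * x)
  expect_equal(fit$slope, -0.5, tolerance = 1e-12)
  expect_equal(fit$intercept, 2, tolerance = 1e-12)
  expect_equal(fit$r, -1, tolerance = 1e-12)

  set.seed(77)
  expect_lt(abs(linear_effect(rnorm(2000), rnorm(2000))$r), 0.08)
  expect_error(linear_effect(rep(1, 10), rnorm(10)), "constant")

  # the generator's TTA-vs-clr_P slope is recovered within 2 SE at n = 80
  trial <- fixture_trial()
  clr <- fixture_clr()
  fit2 <- linear_effect(clr$clr_P, trial$records$tta)
  se <- summary(fit2$fit)$coefficients["x", "Std. Error"]
  expect_lt(abs(fit2$slope - trial$truth$ttap_slope), 2 * se)
})
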