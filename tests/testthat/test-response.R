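test_that("univariate ranking reproduces the regression F statistic", {
  set.seed(21)
  n <- 80
  x <- data.frame(a = rnorm(n), b = rnorm(n), c = rnorm(n))
  y <- 0.8 * x$a + rnorm(n)
  rk <- univariate_rank(x, y)
  # oracle: full regression ANOVA per feature
  for (j in seq_along(x)) {
    f_oracle <- anova(lm(y ~ x[[j]]))[["F value"]][1]
    expect_equal(rk$score[j], f_oracle, tolerance = 1e-9)
  }
  # closed form at r = 0.7, n = 80: 78 * 0.49 / 0.51
  expect_equal((n - 2) * 0.49 / 0.51, 74.94, tolerance = 1e-2)

  # affine rescaling of a feature changes nothing
  x2 <- x; x2$a <- 100 * x2$a - 7
  expect_equal(univariate_rank(x2, y)$score, rk$score, tolerance = 1e-9)

  # a feature identical to the target hits the capped sentinel
  rk_id <- univariate_rank(data.frame(t = y), y)
  expect_equal(rk_id$score, 1e6)

  x$flat <- 1
  expect_warning(rk3 <- univariate_rank(x, y), "constant features")
  expect_equal(rk3$score[4], 0)
  expect_warning(rk4 <- univariate_rank(x[1:3], rep(2, n)),
                 "constant target")
  expect_true(all(rk4$score == 0))
})

test_that("ranking tables cover every target and feature", {
  trial <- fixture_trial()
  clr <- fixture_clr()
  feats <- data.frame(dose = trial$records$dose,
                      clr[c("clr_N", "clr_P", "clr_Cu")])
  tab <- univariate_rank_table(feats, trial$records[c("yield", "tta")])
  expect_equal(dim(tab), c(2, 4))
  expect_true(all(tab >= 0))
  # TTA is driven by clr_P in the generator: it should dominate its row
  expect_equal(names(which.max(unlist(tab["tta", ]))), "clr_P")
})

test_that("orthogonal polynomial contrasts are orthogonal on 5 equally
          spaced doses", {
  cp <- contr.poly(5)
  expect_equal(crossprod(cp[, 1], cp[, 2])[1, 1], 0, tolerance = 1e-12)
  expect_equal(colSums(cp), c(.L = 0, .Q = 0, .C = 0, `^4` = 0),
               tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("dose trends flag the generated quadratic and report CV", {
  # a strong noise-free-ish quadratic over 4 blocks
  set.seed(33)
  doses <- c(0, 40, 80, 120, 160)
  d <- expand.grid(dose = doses, block = 1:4)
  d$year <- 2015
  d$yield <- 18 + 0.25 * d$dose - 0.0015 * d$dose^2 +
    c(-0.5, 0, 0.2, 0.3)[d$block] + rnorm(20, 0, 0.8)
  tr <- dose_trend(d, "yield")
  expect_true(tr$quadratic_sig)
  expect_equal(tr$dose_max, 80)
  expect_gt(tr$cv_percent, 0)
  expect_lt(tr$cv_percent, 15)

  # identical values: nothing significant and CV = 0
  d$yield <- 10
  tr0 <- dose_trend(d, "yield")
  expect_false(tr0$linear_sig)
  expect_false(tr0$quadratic_sig)
  expect_equal(tr0$cv_percent, 0)

  # fewer than three dose levels cannot carry a quadratic contrast
  expect_error(dose_trend(d[d$dose %in% c(0, 40), ], "yield"),
               "dose level")
})

test_that("the dose of maximum observed mean is located", {
  expect_equal(dose_of_maximum(c(0, 40, 80, 120, 160),
                               c(20.7, 26.0, 35.4, 28.1, 24.3)), 80)
  expect_error(dose_of_maximum(1:3, 1:2), "lengths differ")
})

test_that("variance shares sum to one and attribute pure signals", {
  trial <- fixture_trial()
  vp <- variance_partition(trial$records, "yield")
  expect_equal(sum(vp), 1, tolerance = 1e-9)
  expect_equal(names(vp), c("season", "dose", "block", "residual"))

  # permutation invariance
  perm <- sample(nrow(trial$records))
  vp2 <- variance_partition(trial$records[perm, ], "yield")
  expect_equal(as.numeric(vp2), as.numeric(vp), tolerance = 1e-12)

  # value depending only on the season puts all variance there
  rec <- trial$records
  rec$v <- as.numeric(factor(rec$year)) * 10
  vp3 <- variance_partition(rec, "v")
  expect_equal(vp3[["season"]], 1, tolerance = 1e-9)

  # pure noise leaves little for season or dose
  set.seed(8)
  rec$noise <- rnorm(nrow(rec))
  vp4 <- variance_partition(rec, "noise")
  expect_lt(vp4[["season"]], 0.1)
  expect_lt(vp4[["dose"]], 0.1)

  expect_error(variance_partition(rec[rec$year == 2014, ], "yield"),
               "at least 2 seasons")
})

test_that("variance partition recovers the generator's season share", {
  trial <- fixture_trial()
  vp <- variance_partition(trial$records, "yield")
  expect_lt(abs(vp[["season"]] - trial$truth$variance_shares[["season"]]),
            0.05)
})

test_that("carryover training uses prior seasons and the test season
          counts match the design", {
  trial <- fixture_trial()
  fit <- carryover_fit_predict(trial, "yield", cutoff = 16, nrounds = 50)
  expect_equal(fit$n_train, 60)
  expect_equal(fit$n_test, 20)
  expect_equal(fit$test_year, 2017)
  expect_equal(nrow(fit$dose_curve), 5)
  expect_true(fit$p_high >= 0 && fit$p_high <= 1)

  # broken prior-season linkage is rejected with the orphan named
  broken <- trial
  broken$baseline$records <- broken$baseline$records[-1, ]
  expect_error(carryover_fit_predict(broken, "yield"),
               "missing prior-season linkage")
})

test_that("without season effects or noise the learner reproduces the
          dose-response curve", {
  truth <- ground_truth(
    dose_response_coeffs = list(`2014` = c(20, 0.25, -0.0015),
                                `2015` = c(20.2, 0.25, -0.0015),
                                `2016` = c(19.8, 0.25, -0.0015),
                                `2017` = c(20.1, 0.25, -0.0015)),
    variance_shares = c(season = 0.002, dose = 0.998, block = 0,
                        residual = 0),
    cu_yield_slope = 0, carryover_coeff = 0)
  trial <- simulate_trial(trial_design(), truth, seed = 10)
  fit <- carryover_fit_predict(trial, "yield", nrounds = 300)
  actual_curve <- tapply(trial$records$yield[trial$records$year == 2017],
                         trial$records$dose[trial$records$year == 2017],
                         mean)
  expect_equal(as.numeric(fit$dose_curve$predicted),
               as.numeric(actual_curve), tolerance = 0.05)
  expect_gt(cor(fit$predictions$predicted, fit$predictions$actual), 0.95)
})

test_that("modelling the prior yield pays off when carryover is real", {
  truth <- ground_truth(
    dose_response_coeffs = list(`2014` = c(24, 0.1, -6e-4),
                                `2015` = c(25, 0.1, -6e-4),
                                `2016` = c(24.5, 0.1, -6e-4),
                                `2017` = c(25.5, 0.1, -6e-4)),
    variance_shares = c(season = 0.05, dose = 0.15, block = 0.4,
                        residual = 0.4),
    cu_yield_slope = 0, carryover_coeff = 0.5)
  wins <- 0L
  n_rep <- 10
  rel <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    trial <- simulate_trial(trial_design(), truth, seed = 2000 + r)
    with_prior <- carryover_fit_predict(trial, "yield", nrounds = 120,
                                        use_prior_target = TRUE, seed = r)
    without <- carryover_fit_predict(trial, "yield", nrounds = 120,
                                     use_prior_target = FALSE, seed = r)
    rel[r] <- with_prior$rmse / without$rmse
    if (with_prior$rmse < without$rmse) wins <- wins + 1L
  }
  # prior-yield feature lowers held-out RMSE by a clear margin on average
  expect_lt(mean(rel), 0.8)
  expect_gte(wins, 8)
})
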