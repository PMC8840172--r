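# Shared fixtures, built once per test run.

.fixtures <- new.env(parent = emptyenv())

fixture_weather <- function() {
  if (is.null(.fixtures$weather))
    .fixtures$weather <- simulate_weather(weather_params(), 2014:2017,
                                          seed = 1)
  .fixtures$weather
}

fixture_trial <- function() {
  if (is.null(.fixtures$trial))
    .fixtures$trial <- simulate_trial(trial_design(), ground_truth(),
                                      weather = NULL, seed = 1)
  .fixtures$trial
}

fixture_report <- function() {
  if (is.null(.fixtures$report)) {
    t0 <- Sys.time()
    .fixtures$report <- suppressMessages(suppressWarnings(
      run_pipeline(seed = 5)))
    .fixtures$report_elapsed <-
      as.numeric(difftime(Sys.time(), t0, units = "secs"))
  }
  .fixtures$report
}

fixture_clr <- function() {
  if (is.null(.fixtures$clr))
    .fixtures$clr <- clr_transform(fixture_trial()$foliar)
  .fixtures$clr
}

# random strictly positive foliar tables on the 1000 g/kg unit
random_foliar <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(N = runif(n, 20, 35), P = runif(n, 1, 6), K = runif(n, 15, 35),
             Ca = runif(n, 10, 25), Mg = runif(n, 2, 8),
             Cu = runif(n, 2, 15), Fe = runif(n, 40, 120),
             Mn = runif(n, 50, 130), Zn = runif(n, 10, 60),
             B = runif(n, 20, 60))
}

# noise-free piecewise response with the breakpoint in the candidate grid
make_plateau_data <- function(bp, form = c("trend-plateau", "plateau-trend"),
                              slope = 5, level = 10, span = 0.8, n = 33) {
  form <- match.arg(form)
  x <- sort(unique(c(seq(bp - span, bp + span, length.out = n), bp)))
  y <- if (form == "trend-plateau")
    ifelse(x < bp, level + slope * (x - bp), level)
  else
    ifelse(x > bp, level + slope * (x - bp), level)
  list(x = x, y = y)
}

# printed confusion counts of the reference norm table (yield, pulp
# firmness, TTA, carotenoids rows)
reference_confusions <- function() {
  list(yield = list(TN = 58, TP = 20, FN = 2, FP = 0),
       pulp_firmness = list(TN = 39, TP = 18, FN = 1, FP = 2),
       tta = list(TN = 49, TP = 10, FN = 13, FP = 8),
       carotenoids = list(TN = 17, TP = 58, FN = 3, FP = 2))
}

# published clr norms (high-yield column): means and SDs per component
reference_clr_means <- function() {
  c(N = 3.16, P = 0.866, K = 3.06, Ca = 2.70, Mg = 1.27, Cu = -5.10,
    Fe = -2.70, Mn = -2.63, Zn = -3.69, B = -3.57, Fv = 6.62)
}
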