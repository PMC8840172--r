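#' Trial design for an N-rate orchard experiment
#'
#' Defaults reproduce a 4-season randomized complete block trial with five
#' N rates and four blocks (80 experimental-unit-years), planted at
#' 6 m between rows and 1.5 m within rows.
#'
#' @param years integer vector of cropping seasons.
#' @param doses N rates in kg N/ha, strictly increasing, non-negative.
#' @param blocks number of blocks (>= 2).
#' @param plants_per_plot plants per experimental unit.
#' @param row_spacing_m,inrow_spacing_m plant spacing in metres.
#' @return list of class `trial_design`.
#' @export
trial_design <- function(years = 2014:2017,
                         doses = c(0, 40, 80, 120, 160),
                         blocks = 4,
                         plants_per_plot = 4,
                         row_spacing_m = 6,
                         inrow_spacing_m = 1.5) {
  if (any(doses < 0) || is.unsorted(doses, strictly = TRUE))
    stop("doses must be non-negative and strictly increasing")
  if (blocks < 2) stop("at least 2 blocks are required")
  if (row_spacing_m <= 0 || inrow_spacing_m <= 0)
    stop("spacings must be positive")
  structure(list(years = as.integer(years), doses = doses,
                 blocks = as.integer(blocks),
                 plants_per_plot = as.integer(plants_per_plot),
                 row_spacing_m = row_spacing_m,
                 inrow_spacing_m = inrow_spacing_m),
            class = "trial_design")
}

#' Planting density from spacing
#'
#' @param design a [trial_design()].
#' @return trees per hectare (integer, floor of 10000 / (row * in-row)).
#' @export
#' @examples
#' planting_density(trial_design())  # 1111 trees/ha
planting_density <- function(design) {
  as.integer(10000 / (design$row_spacing_m * design$inrow_spacing_m))
}

#' Ground-truth parameters of the synthetic trial
#'
#' Encodes the statistical structure the generator realizes: per-season
#' quadratic yield response to N dose, variance shares of season / dose /
#' block / residual, a logistic-normal foliar composition model in clr space,
#' two breakpoint dependencies (yield and antioxidants on clr_Cu, pulp
#' firmness on clr_P), a linear TTA dependence on clr_P, and a lag-1 yield
#' carryover. Defaults describe a temperate peach N trial in which the
#' cropping season dominates yield variance (73%), dose contributes 7%, and
#' the 2017-style failure year depresses every season-sensitive trait.
#'
#' @param dose_response_coeffs list (one element per season) of quadratic
#'   coefficients `c(intercept, linear, quadratic)` on the ton/ha yield scale.
#' @param variance_shares named fractions `season, dose, block, residual` of
#'   total yield variance; must sum to 1.
#' @param clr_location,clr_spread length-11 clr mean and SD per component
#'   (order [nutrient_components()]); `clr_location` must sum to 0.
#' @param cu_breakpoint clr_Cu below which yield and antioxidant content
#'   decline linearly (clr units).
#' @param cu_yield_slope fractional yield loss per clr unit of Cu deficit.
#' @param tac_cu_slope antioxidant loss (mg/100 g) per clr unit of Cu deficit.
#' @param p_breakpoint clr_P above which pulp firmness gains a step.
#' @param firmness_step pulp-firmness gain (N) above `p_breakpoint`.
#' @param ttap_slope TTA change (% citric acid) per clr_P unit (negative:
#'   higher foliar P gives less acid fruit).
#' @param carryover_coeff effect of a plot's previous-season yield deviation
#'   on its current-season yield.
#' @param noise_sd named list of residual SDs for the quality targets, in
#'   each target's own units.
#' @param seed default random seed used when the simulation functions are not
#'   given one explicitly.
#' @return list of class `ground_truth`.
#' @export
ground_truth <- function(
    dose_response_coeffs = list(
      `2014` = c(26.091, 0.036679, -0.000353),
      `2015` = c(17.683, 0.156107, -0.000674),
      `2016` = c(20.054, 0.272536, -0.001558),
      `2017` = c(4.214, 0.015286, 0.000098)),
    variance_shares = c(season = 0.73, dose = 0.07,
                        block = 0.05, residual = 0.15),
    clr_location = local({
      # published-style clr norms for a high-yield population; printed means
      # sum to -0.014 from rounding, so recentre exactly onto the simplex
      m <- c(3.16, 0.866, 3.06, 2.70, 1.27,
             -5.10, -2.70, -2.63, -3.69, -3.57, 6.62)
      m - mean(m)
    }),
    clr_spread = c(0.108, 0.420, 0.183, 0.168, 0.330,
                   0.209, 0.228, 0.169, 0.308, 0.181, 0.087),
    cu_breakpoint = -5.410,
    cu_yield_slope = 0.5,
    tac_cu_slope = 400,
    p_breakpoint = 0.556,
    firmness_step = 0.6,
    ttap_slope = -0.3,
    carryover_coeff = 0.3,
    noise_sd = list(skin_firmness = 0.8, pulp_firmness = 0.25, hue = 2,
                    chroma = 2, tss = 0.7, tta = 0.08, phenolics = 30,
                    carotenoids = 0.5, tac = 80, fruit_mass = 8),
    seed = 42) {
  vs <- variance_shares
  if (abs(sum(vs) - 1) > 1e-9) stop("variance_shares must sum to 1")
  if (any(vs < 0)) stop("variance_shares must be non-negative")
  if (abs(sum(clr_location)) > 1e-9) stop("clr_location must sum to 0")
  if (any(clr_spread <= 0)) stop("clr_spread values must be positive")
  if (length(clr_location) != 11L || length(clr_spread) != 11L)
    stop("clr_location and clr_spread must have 11 components")
  structure(list(dose_response_coeffs = dose_response_coeffs,
                 variance_shares = vs,
                 clr_location = stats::setNames(clr_location, .parts),
                 clr_spread = stats::setNames(clr_spread, .parts),
                 cu_breakpoint = cu_breakpoint,
                 cu_yield_slope = cu_yield_slope,
                 tac_cu_slope = tac_cu_slope,
                 p_breakpoint = p_breakpoint,
                 firmness_step = firmness_step,
                 ttap_slope = ttap_slope,
                 carryover_coeff = carryover_coeff,
                 noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "ground_truth")
}

#' Weather generator parameters
#'
#' Defaults emulate a humid subtropical ("Cfa") site in the Southern
#' Hemisphere: 18 deg C annual mean, 6 deg C seasonal half-amplitude
#' (warmest mid-January), 8 deg C mean diurnal range, 1509 mm annual
#' rainfall. Bloom and harvest dates default to late-July/early-August bloom
#' and December harvest.
#'
#' @param mean_annual_temp annual mean temperature, deg C.
#' @param seasonal_amplitude seasonal half-amplitude of the daily mean, deg C.
#' @param diurnal_range mean Tmax - Tmin, deg C.
#' @param daily_noise_sd SD of day-to-day temperature noise, deg C.
#' @param annual_rain_mm expected annual rainfall depth, mm.
#' @param wet_day_prob probability any day is wet.
#' @param bloom_dates,harvest_dates named character vectors (names = years,
#'   ISO dates) overriding the default phenology.
#' @return list of class `weather_params`.
#' @export
weather_params <- function(mean_annual_temp = 18,
                           seasonal_amplitude = 6,
                           diurnal_range = 8,
                           daily_noise_sd = 2,
                           annual_rain_mm = 1509,
                           wet_day_prob = 0.4,
                           bloom_dates = c(`2014` = "2014-07-29",
                                           `2015` = "2015-08-01",
                                           `2016` = "2016-08-03",
                                           `2017` = "2017-07-18"),
                           harvest_dates = c(`2014` = "2014-12-16",
                                             `2015` = "2015-12-20",
                                             `2016` = "2016-12-22",
                                             `2017` = "2017-11-30")) {
  if (diurnal_range <= 0) stop("diurnal_range must be positive")
  if (seasonal_amplitude < 0 || daily_noise_sd < 0)
    stop("amplitude and noise sd must be non-negative")
  if (annual_rain_mm < 0) stop("annual rainfall must be non-negative")
  structure(list(mean_annual_temp = mean_annual_temp,
                 seasonal_amplitude = seasonal_amplitude,
                 diurnal_range = diurnal_range,
                 daily_noise_sd = daily_noise_sd,
                 annual_rain_mm = annual_rain_mm,
                 wet_day_prob = wet_day_prob,
                 bloom_dates = bloom_dates,
                 harvest_dates = harvest_dates),
            class = "weather_params")
}

#' Bloom-to-harvest windows for a set of seasons
#'
#' @param params a [weather_params()].
#' @param years integer vector of seasons.
#' @return named list of [season_window()]s. Years without stated phenology
#'   default to Aug 1 bloom and Dec 15 harvest.
#' @export
season_windows <- function(params, years) {
  out <- lapply(as.character(years), function(yr) {
    bloom <- if (yr %in% names(params$bloom_dates))
      params$bloom_dates[[yr]] else paste0(yr, "-08-01")
    harvest <- if (yr %in% names(params$harvest_dates))
      params$harvest_dates[[yr]] else paste0(yr, "-12-15")
    season_window(bloom, harvest)
  })
  stats::setNames(out, as.character(years))
}

#' Simulate daily and hourly weather
#'
#' Daily mean temperature follows a seasonal cosine (warmest mid-January,
#' Southern Hemisphere) plus Gaussian day-to-day noise; Tmin/Tmax straddle it
#' by half the diurnal range. Hourly temperatures interpolate Tmin (dawn,
#' 06:00) to Tmax (15:00) with a piecewise cosine diurnal curve. Rainfall is
#' generated as gamma-distributed wet-day amounts with constant wet-day
#' probability, scaled so the expected annual depth matches `annual_rain_mm`.
#'
#' @param params a [weather_params()].
#' @param years either a count of years (starting 2014) or an integer vector
#'   of calendar years.
#' @param seed integer random seed.
#' @return list of class `weather_sim` with `daily` (`date, tmin, tmax,
#'   rain`) and `hourly` (`datetime, temp`) data.frames.
#' @export
simulate_weather <- function(params = weather_params(), years = 4, seed = 1) {
  if (length(years) == 1L && years < 1000) {
    if (years < 1) stop("years must be >= 1")
    years <- 2014L + seq_len(years) - 1L
  }
  years <- as.integer(years)
  set.seed(seed)
  daily_list <- vector("list", length(years))
  for (k in seq_along(years)) {
    yr <- years[k]
    dates <- seq(as.Date(sprintf("%d-01-01", yr)),
                 as.Date(sprintf("%d-12-31", yr)), by = "day")
    doy <- as.integer(format(dates, "%j"))
    n <- length(dates)
    seasonal <- params$mean_annual_temp +
      params$seasonal_amplitude * cos(2 * pi * (doy - 15) / 365.25)
    tmean <- seasonal + stats::rnorm(n, 0, params$daily_noise_sd)
    half <- pmax(params$diurnal_range / 2 +
                   stats::rnorm(n, 0, params$daily_noise_sd / 2), 0.5)
    wet <- stats::runif(n) < params$wet_day_prob
    mean_amount <- if (params$wet_day_prob > 0)
      params$annual_rain_mm / (365.25 * params$wet_day_prob) else 0
    rain <- numeric(n)
    if (mean_amount > 0)
      rain[wet] <- stats::rgamma(sum(wet), shape = 0.8,
                                 scale = mean_amount / 0.8)
    daily_list[[k]] <- data.frame(date = dates, tmin = tmean - half,
                                  tmax = tmean + half, rain = rain)
  }
  daily <- do.call(rbind, daily_list)
  hourly <- .diurnal_interpolate(daily)
  structure(list(daily = daily, hourly = hourly, params = params,
                 seed = as.integer(seed)),
            class = "weather_sim")
}

# Piecewise-cosine diurnal interpolation anchored at Tmin (06:00) and
# Tmax (15:00); evening/night hours relax from Tmax back toward Tmin.
.diurnal_interpolate <- function(daily) {
  n <- nrow(daily)
  h <- 0:23
  rise <- h >= 6 & h <= 15
  frac <- numeric(24)
  frac[rise] <- (1 - cos(pi * (h[rise] - 6) / 9)) / 2       # 0 at dawn, 1 at 15h
  frac[!rise] <- (1 + cos(pi * ((h[!rise] - 15) %% 24) / 15)) / 2
  tmin <- rep(daily$tmin, each = 24)
  tmax <- rep(daily$tmax, each = 24)
  temp <- tmin + (tmax - tmin) * rep(frac, times = n)
  datetime <- rep(as.POSIXct(paste(daily$date, "00:00:00"), tz = "UTC"),
                  each = 24) + rep(h * 3600, times = n)
  data.frame(datetime = datetime, temp = temp)
}

#' Simulate a multi-season N-rate trial with known ground truth
#'
#' Builds one record per season x dose x block. Yields realize the
#' ground-truth variance shares exactly in expectation: the season and dose
#' main effects of the per-season quadratic surface are rescaled to their
#' specified variance shares, the season x dose interaction is folded into
#' the residual budget, block effects are an exactly-standardized random
#' pattern, and iid noise fills the remaining residual variance. Foliar
#' compositions are drawn logistic-normally around `clr_location`, a plot's
#' yield is shrunk when its clr_Cu falls below `cu_breakpoint`, TTA declines
#' linearly in clr_P, pulp firmness gains a step above `p_breakpoint`, and
#' each season's yield carries over a fraction of the previous season's
#' deviation. A pre-trial baseline season (uniform management) is emitted so
#' every first-season record has prior-season features for the carryover
#' stage.
#'
#' @param design a [trial_design()].
#' @param truth a [ground_truth()].
#' @param weather a `weather_sim` covering all design years (only checked
#'   for coverage here; climate indices are computed downstream).
#' @param seed integer seed; defaults to `truth$seed`.
#' @return object of class `peach_trial`: list with `records` (trial
#'   records), `foliar` (matching compositions, mg/kg micros), `baseline`
#'   (pre-trial season records + foliar), `design`, `truth`, `weather`.
#' @export
simulate_trial <- function(design = trial_design(), truth = ground_truth(),
                           weather = NULL, seed = truth$seed) {
  if (!inherits(design, "trial_design")) stop("design must be a trial_design")
  if (!inherits(truth, "ground_truth")) stop("truth must be a ground_truth")
  if (!is.null(weather)) {
    wyears <- unique(as.integer(format(as.Date(weather$daily$date), "%Y")))
    missing_years <- setdiff(design$years, wyears)
    if (length(missing_years))
      stop("weather series does not cover design years: ",
           paste(missing_years, collapse = ", "))
  }
  set.seed(seed)
  years <- design$years
  doses <- design$doses
  nb <- design$blocks
  ny <- length(years)
  nd <- length(doses)
  n <- ny * nd * nb

  # quadratic response surface and its balanced two-way decomposition
  coeffs <- truth$dose_response_coeffs
  if (length(coeffs) != ny)
    stop("dose_response_coeffs must have one element per season")
  surface <- t(vapply(coeffs, function(b)
    b[1] + b[2] * doses + b[3] * doses^2, numeric(nd)))
  grand <- mean(surface)
  year_main <- rowMeans(surface) - grand
  dose_main <- colMeans(surface) - grand
  inter <- surface - grand - outer(year_main, rep(1, nd)) -
    outer(rep(1, ny), dose_main)

  vs <- truth$variance_shares
  v_year_raw <- mean(year_main^2)
  v_dose_raw <- mean(dose_main^2)
  if (v_year_raw <= 0) stop("season effects are all zero in the coefficients")
  v_sig <- v_year_raw + v_dose_raw + mean(inter^2)
  total_var <- v_sig / (vs[["season"]] + vs[["dose"]])
  f_year <- sqrt(vs[["season"]] * total_var / v_year_raw)
  f_dose <- if (v_dose_raw > 0)
    sqrt(vs[["dose"]] * total_var / v_dose_raw) else 0
  year_eff <- f_year * year_main
  dose_eff <- f_dose * dose_main
  inter_eff <- f_dose * inter
  v_res_target <- vs[["residual"]] * total_var
  sd_iid <- sqrt(max(v_res_target - mean(inter_eff^2), 0))

  block_eff <- stats::rnorm(nb)
  block_eff <- block_eff - mean(block_eff)
  ms <- mean(block_eff^2)
  block_eff <- if (ms > 0)
    block_eff / sqrt(ms) * sqrt(vs[["block"]] * total_var) else
      rep(0, nb)

  rec <- expand.grid(block = seq_len(nb), dose = doses, year = years,
                     KEEP.OUT.ATTRS = FALSE)[, c("year", "dose", "block")]
  rec <- rec[order(rec$year, rec$dose, rec$block), , drop = FALSE]
  rownames(rec) <- NULL
  rec$plot <- paste0("d", rec$dose, "_b", rec$block)
  iy <- match(rec$year, years)
  id <- match(rec$dose, doses)

  # foliar compositions: independent clr Gaussians projected to zero sum
  z <- matrix(stats::rnorm(n * 11L, mean = rep(truth$clr_location, each = n),
                           sd = rep(truth$clr_spread, each = n)),
              nrow = n, ncol = 11L, dimnames = list(NULL, .parts))
  z <- z - rowMeans(z)
  foliar <- clr_inverse(z, unit_total = 1000)

  # baseline (pre-trial) season: uniform management, same plots
  nb_rows <- nd * nb
  zb <- matrix(stats::rnorm(nb_rows * 11L,
                            mean = rep(truth$clr_location, each = nb_rows),
                            sd = rep(truth$clr_spread, each = nb_rows)),
               nrow = nb_rows, ncol = 11L, dimnames = list(NULL, .parts))
  zb <- zb - rowMeans(zb)
  base_rec <- rec[rec$year == years[1], c("dose", "block", "plot")]
  base_rec$year <- years[1] - 1L
  base_rec$dose_applied <- 90  # uniform pre-trial N regime, kg N/ha
  base_rec$yield <- grand + block_eff[base_rec$block] +
    stats::rnorm(nb_rows, 0, sd_iid)
  baseline <- list(records = base_rec[, c("year", "dose", "block", "plot",
                                          "dose_applied", "yield")],
                   foliar = clr_inverse(zb, unit_total = 1000))

  # yield with Cu plateau factor and lag-1 carryover
  noise <- stats::rnorm(n, 0, sd_iid)
  base_yield <- grand + year_eff[iy] + dose_eff[id] +
    inter_eff[cbind(iy, id)] + block_eff[rec$block] + noise
  cu_deficit <- pmin(z[, "Cu"] - truth$cu_breakpoint, 0)
  cu_factor <- pmax(1 + truth$cu_yield_slope * cu_deficit, 0.2)
  yield <- base_yield * cu_factor
  prev_dev <- numeric(n)
  for (k in seq_along(years)) {
    rows <- which(rec$year == years[k])
    if (k == 1L) {
      pv <- baseline$records$yield[match(rec$plot[rows],
                                         baseline$records$plot)]
    } else {
      prev_rows <- which(rec$year == years[k - 1L])
      pv <- yield[prev_rows][match(rec$plot[rows], rec$plot[prev_rows])]
    }
    # plot-idiosyncratic deviation: prior yield relative to its own
    # season x dose cell mean, so design-factor variances stay intact
    prev_dev[rows] <- pv - stats::ave(pv, rec$dose[rows])
    yield[rows] <- yield[rows] + truth$carryover_coeff * prev_dev[rows]
  }
  yield <- pmax(yield, 0.1)
  rec$yield <- yield
  rec$prev_yield_dev <- prev_dev

  # quality targets: season-sensitive bases plus composition-driven terms
  ns <- truth$noise_sd
  yr_fx <- list(skin_firmness = c(0.3, 0.2, 0.5, -1.8),
                hue = c(1, 2, 1.5, -6),
                chroma = c(1, 1.5, 1, -5),
                tss = c(0.3, 0.5, 0.4, -1.5),
                phenolics = c(10, 5, 15, -35),
                carotenoids = c(0.2, 0.3, 0.3, -1.1),
                tac = c(40, 60, 50, -300),
                fruit_mass = c(-5, 5, -35, 25))
  fx <- function(target) {
    v <- yr_fx[[target]]
    if (length(v) != ny) v <- rep_len(v, ny)
    v[iy]
  }
  rec$fruit_mass <- 110 + fx("fruit_mass") + stats::rnorm(n, 0, ns$fruit_mass)
  kg_per_tree <- rec$yield * 1000 / planting_density(design)
  rec$fruit_count <- round(pmax(kg_per_tree * 1000 / rec$fruit_mass, 1))
  rec$skin_firmness <- 9.5 + fx("skin_firmness") +
    stats::rnorm(n, 0, ns$skin_firmness)
  rec$pulp_firmness <- 2.2 +
    truth$firmness_step * (z[, "P"] > truth$p_breakpoint) +
    stats::rnorm(n, 0, ns$pulp_firmness)
  rec$hue <- 84 + fx("hue") + stats::rnorm(n, 0, ns$hue)
  rec$chroma <- 53 + fx("chroma") + stats::rnorm(n, 0, ns$chroma)
  rec$tss <- 11.5 + fx("tss") + stats::rnorm(n, 0, ns$tss)
  rec$tta <- 0.9 + truth$ttap_slope *
    (z[, "P"] - truth$clr_location[["P"]]) + stats::rnorm(n, 0, ns$tta)
  rec$tta <- pmax(rec$tta, 0.05)
  rec$phenolics <- 300 + fx("phenolics") + stats::rnorm(n, 0, ns$phenolics)
  rec$carotenoids <- 6.5 + fx("carotenoids") +
    stats::rnorm(n, 0, ns$carotenoids)
  rec$tac <- 2000 + fx("tac") + truth$tac_cu_slope * cu_deficit +
    stats::rnorm(n, 0, ns$tac)

  structure(list(records = rec, foliar = foliar, baseline = baseline,
                 design = design, truth = truth, weather = weather,
                 seed = as.integer(seed)),
            class = "peach_trial")
}

#' @export
print.peach_trial <- function(x, ...) {
  cat("Synthetic orchard N-rate trial\n")
  cat(sprintf("  seasons: %s\n", paste(x$design$years, collapse = ", ")))
  cat(sprintf("  N rates: %s kg N/ha, %d blocks -> %d records\n",
              paste(x$design$doses, collapse = ", "), x$design$blocks,
              nrow(x$records)))
  ym <- tapply(x$records$yield, x$records$year, mean)
  cat("  mean yield by season (ton/ha):\n")
  print(round(ym, 1))
  invisible(x)
}

#' @export
print.ground_truth <- function(x, ...) {
  cat("Ground truth for the synthetic trial\n")
  cat("  variance shares:",
      paste(sprintf("%s=%.2f", names(x$variance_shares), x$variance_shares),
            collapse = ", "), "\n")
  cat(sprintf("  clr_Cu breakpoint %.3f, clr_P breakpoint %.3f, TTA slope %.2f\n",
              x$cu_breakpoint, x$p_breakpoint, x$ttap_slope))
  cat(sprintf("  carryover coefficient %.2f\n", x$carryover_coeff))
  invisible(x)
}
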