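#' Default target specifications
#'
#' The ten yield and fruit-quality targets with their agronomic cutoffs:
#' yield 16 ton/ha, skin firmness 8.82 N, pulp firmness 2.5 N, hue 80,
#' chroma 50, TSS 10.5, TTA 0.9% (low is good), phenolics 280,
#' carotenoids 5.9, total antioxidant content 1800 mg/100 g.
#'
#' @return named list of [target_spec()]s.
#' @export
default_targets <- function() {
  specs <- list(
    target_spec("yield", 16, "high-is-good"),
    target_spec("skin_firmness", 8.82, "high-is-good"),
    target_spec("pulp_firmness", 2.5, "high-is-good"),
    target_spec("hue", 80, "high-is-good"),
    target_spec("chroma", 50, "high-is-good"),
    target_spec("tss", 10.5, "high-is-good"),
    target_spec("tta", 0.9, "low-is-good"),
    target_spec("phenolics", 280, "high-is-good"),
    target_spec("carotenoids", 5.9, "high-is-good"),
    target_spec("tac", 1800, "high-is-good"))
  stats::setNames(specs, vapply(specs, `[[`, character(1), "name"))
}

#' Pipeline configuration
#'
#' Collects every stage's parameters. All defaults reproduce the package's
#' reference synthetic trial.
#'
#' @param design a [trial_design()].
#' @param truth a [ground_truth()].
#' @param weather a [weather_params()].
#' @param targets named list of [target_spec()]s.
#' @param cv_folds stratified cross-validation folds.
#' @param gdd a [gdd_config()].
#' @param chill_threshold chilling-hour threshold, deg C.
#' @param standards_mode `"parametric-ci"` or `"empirical-quantile"`.
#' @param alpha two-tailed level for concentration ranges.
#' @param coverage sufficiency-range density coverage.
#' @param n_boot bootstrap resamples for critical values.
#' @param standards_target target whose true negatives form the norm
#'   population for the standards block.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(design = trial_design(),
                            truth = ground_truth(),
                            weather = weather_params(),
                            targets = default_targets(),
                            cv_folds = 10,
                            gdd = gdd_config(),
                            chill_threshold = 7.2,
                            standards_mode = c("parametric-ci",
                                               "empirical-quantile"),
                            alpha = 0.01,
                            coverage = 0.90,
                            n_boot = 200,
                            standards_target = "yield") {
  standards_mode <- match.arg(standards_mode)
  for (tg in targets)
    if (!inherits(tg, "target_spec"))
      stop("every target must be a target_spec")
  if (!standards_target %in% names(targets))
    stop("standards_target '", standards_target, "' has no target_spec")
  structure(list(design = design, truth = truth, weather = weather,
                 targets = targets, cv_folds = cv_folds, gdd = gdd,
                 chill_threshold = chill_threshold,
                 standards_mode = standards_mode, alpha = alpha,
                 coverage = coverage, n_boot = n_boot,
                 standards_target = standards_target),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Recognized keys: `targets` (list of `name`, `cutoff`, `orientation`
#' entries; a missing cutoff is a validation error naming the target),
#' `cv_folds`, `standards_mode`, `alpha`, `coverage`, `n_boot`,
#' `standards_target`, `gdd` (`Tbase`, `TLT`, `TUT`), `chill_threshold`.
#' Unrecognized keys are rejected.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- c("targets", "cv_folds", "standards_mode", "alpha", "coverage",
             "n_boot", "standards_target", "gdd", "chill_threshold")
  extra <- setdiff(names(raw), known)
  if (length(extra)) stop("unknown config keys: ", paste(extra, collapse = ", "))
  args <- list()
  if (!is.null(raw$targets)) {
    args$targets <- stats::setNames(lapply(raw$targets, function(t) {
      if (is.null(t$name)) stop("a target entry has no name")
      if (is.null(t$cutoff))
        stop("target '", t$name, "' has no cutoff")
      if (is.null(t$orientation))
        stop("target '", t$name, "' has no orientation")
      target_spec(t$name, t$cutoff, t$orientation)
    }), vapply(raw$targets, `[[`, character(1), "name"))
  }
  if (!is.null(raw$gdd))
    args$gdd <- gdd_config(Tbase = raw$gdd$Tbase %||% 7,
                           TLT = raw$gdd$TLT %||% 7,
                           TUT = raw$gdd$TUT %||% 35)
  for (k in c("cv_folds", "standards_mode", "alpha", "coverage", "n_boot",
              "standards_target", "chill_threshold"))
    if (!is.null(raw[[k]])) args[[k]] <- raw[[k]]
  do.call(pipeline_config, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full diagnosis pipeline on a synthetic trial
#'
#' Sequences every stage: simulate weather and trial, clr-transform the
#' foliar table, compute per-season climate indices, classify every target
#' at its cutoff (k-NN and linear classifier, stratified cross-validation),
#' derive nutrient standards (clr norms, concentration ranges, N sufficiency
#' range) from the true negatives of the standards target, locate the
#' clr_Cu and clr_P critical values, rank features, analyse dose trends and
#' the variance partition, and fit the season-carryover predictor. Fully
#' deterministic given `seed`.
#'
#' @param config a [pipeline_config()].
#' @param seed integer master seed; stage seeds are derived from it.
#' @param outdir optional directory: when given, tables are written as CSV
#'   and a JSON manifest records the completed stages.
#' @param trial optional pre-built `peach_trial` (e.g., from files); when
#'   supplied the simulation stage is skipped.
#' @return object of class `nutriclr_report`.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = 1,
                         outdir = NULL, trial = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  seed <- as.integer(seed)
  stages <- character(0)
  log <- function(stage, fmt, ...) {
    message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
    stages <<- unique(c(stages, stage))
  }

  if (is.null(trial)) {
    log("simulate", "weather for years %s (seed %d)",
        paste(range(config$design$years), collapse = "-"), seed)
    weather <- simulate_weather(config$weather, config$design$years,
                                seed = seed)
    trial <- simulate_trial(config$design, config$truth, weather,
                            seed = seed + 1L)
    log("simulate", "%d trial records, %d foliar specimens",
        nrow(trial$records), nrow(trial$foliar))
  } else {
    weather <- trial$weather
  }
  rec <- trial$records

  log("clr", "transforming %d foliar compositions", nrow(trial$foliar))
  clr <- clr_transform(trial$foliar)

  log("climate", "indices for %d seasons", length(config$design$years))
  windows <- season_windows(config$weather, config$design$years)
  climate <- climate_summary(weather, windows, config$gdd,
                             config$chill_threshold)

  # per-record feature table: season climate + N dose + nutrient balances
  ci <- climate[match(rec$year, climate$year), ]
  features <- data.frame(chill_h = ci$chill_h, gdd2 = ci$gdd2,
                         rain_mm = ci$rain_mm, dose = rec$dose,
                         clr[paste0("clr_", c(.macros, .micros))])

  log("classify", "%d targets, %d-fold stratified CV",
      length(config$targets), config$cv_folds)
  keys <- paste(rec$year, rec$plot, sep = "_")
  classifications <- lapply(config$targets, function(tg)
    classify_target(features, rec[[tg$name]], tg,
                    cv_folds = config$cv_folds, cv_seed = seed + 2L,
                    keys = keys))
  classification_table <- do.call(rbind, lapply(classifications, function(r) {
    b <- r$models[[r$best]]
    data.frame(target = r$target, cutoff = r$cutoff, model = r$best,
               auc = b$auc, ca = b$ca, TN = b$partition$TN,
               TP = b$partition$TP, FN = b$partition$FN,
               FP = b$partition$FP, n = b$partition$n_total)
  }))
  rownames(classification_table) <- NULL

  log("standards", "norms from true negatives of '%s'",
      config$standards_target)
  cls <- classifications[[config$standards_target]]
  part <- cls$models[[cls$best]]$partition
  tn_clr <- select_true_negatives(part, clr[cls$kept, , drop = FALSE])
  standards <- clr_standards(tn_clr)
  ranges <- concentration_ranges(standards, alpha = config$alpha,
                                 mode = config$standards_mode,
                                 tn_table = tn_clr)
  tn_foliar <- trial$foliar[cls$kept, , drop = FALSE][part$index$TN, ,
                                                      drop = FALSE]
  n_range <- sufficiency_range_density(tn_foliar$N,
                                       coverage = config$coverage)

  log("standards", "critical values by linear-plateau fits")
  critical <- list(
    yield_vs_clr_Cu = critical_value_piecewise(
      clr$clr_Cu, rec$yield, n_boot = config$n_boot, seed = seed + 3L),
    tac_vs_clr_Cu = critical_value_piecewise(
      clr$clr_Cu, rec$tac, n_boot = config$n_boot, seed = seed + 4L),
    firmness_vs_clr_P = critical_value_piecewise(
      clr$clr_P, rec$pulp_firmness, n_boot = config$n_boot,
      seed = seed + 5L))
  tta_effect <- linear_effect(clr$clr_P, rec$tta)

  log("rank", "univariate regression scores")
  targets_df <- rec[vapply(config$targets, `[[`, character(1), "name")]
  ranking <- univariate_rank_table(features, targets_df)

  log("respond", "dose trends and variance partition")
  trends <- dose_trend(rec, "yield")
  partition <- variance_partition(rec, "yield")

  log("carryover", "gradient-boosting prediction of the held-out season")
  carry <- carryover_fit_predict(trial, "yield",
                                 cutoff = config$targets$yield$cutoff,
                                 seed = seed + 6L)

  report <- structure(list(seed = seed, config = config, trial = trial,
                           climate = climate,
                           classifications = classifications,
                           classification_table = classification_table,
                           standards = standards, ranges = ranges,
                           n_sufficiency = n_range, critical = critical,
                           tta_effect = tta_effect, ranking = ranking,
                           trends = trends, partition = partition,
                           carryover = carry, stages = stages),
                      class = "nutriclr_report")
  if (!is.null(outdir)) write_report(report, outdir)
  report
}

#' @export
print.nutriclr_report <- function(x, ...) {
  cat("Compositional nutrient diagnosis report\n")
  cat(sprintf("  seed %d; %d records, %d targets\n\n", x$seed,
              nrow(x$trial$records), nrow(x$classification_table)))
  cat("Per-season climate indices:\n")
  print(transform(x$climate, gdd1 = round(gdd1), gdd2 = round(gdd2),
                  rain_mm = round(rain_mm)), row.names = FALSE)
  cat("\nClassification summary (best model per target):\n")
  tab <- x$classification_table
  tab$auc <- round(tab$auc, 3); tab$ca <- round(tab$ca, 3)
  print(tab, row.names = FALSE)
  cat("\n")
  print(x$standards)
  cat(sprintf("\nFoliar N sufficiency range: %.1f to %.1f g/kg\n",
              x$n_sufficiency$low, x$n_sufficiency$high))
  cat(sprintf("Critical clr_Cu for yield: %.3f; for antioxidants: %.3f\n",
              x$critical$yield_vs_clr_Cu$breakpoint,
              x$critical$tac_vs_clr_Cu$breakpoint))
  cat(sprintf("Critical clr_P for pulp firmness: %.3f\n",
              x$critical$firmness_vs_clr_P$breakpoint))
  cat(sprintf("TTA on clr_P: slope %.3f (r = %.2f)\n",
              x$tta_effect$slope, x$tta_effect$r))
  cat("\n")
  print(x$partition)
  cat("\n")
  print(x$trends)
  cat("\n")
  print(x$carryover)
  invisible(x)
}

#' Write a report bundle to delimited-text and JSON files
#'
#' Emits `trial_records.csv`, `foliar.csv`, `weather_daily.csv`,
#' `climate.csv`, `classification.csv`, `standards.csv`, `ranges.csv`,
#' `ranking.csv`, `trends.csv`, `carryover_predictions.csv`, a
#' `truth.json` with the generator parameters, and a `MANIFEST.json`
#' listing completed stages. Input files are never modified.
#'
#' @param report a `nutriclr_report`.
#' @param outdir output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_report <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  w <- function(df, name)
    utils::write.csv(df, file.path(outdir, name), row.names = FALSE,
                     quote = FALSE)
  w(report$trial$records, "trial_records.csv")
  w(report$trial$foliar, "foliar.csv")
  if (!is.null(report$trial$weather))
    w(report$trial$weather$daily, "weather_daily.csv")
  w(report$climate, "climate.csv")
  w(report$classification_table, "classification.csv")
  w(as.data.frame(report$standards), "standards.csv")
  w(report$ranges, "ranges.csv")
  w(cbind(target = rownames(report$ranking), report$ranking), "ranking.csv")
  w(as.data.frame(report$trends), "trends.csv")
  w(report$carryover$predictions, "carryover_predictions.csv")
  truth <- report$trial$truth
  jsonlite::write_json(
    list(variance_shares = as.list(truth$variance_shares),
         clr_location = as.list(truth$clr_location),
         clr_spread = as.list(truth$clr_spread),
         cu_breakpoint = truth$cu_breakpoint,
         p_breakpoint = truth$p_breakpoint,
         ttap_slope = truth$ttap_slope,
         carryover_coeff = truth$carryover_coeff,
         seed = report$seed),
    file.path(outdir, "truth.json"), auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(
    list(seed = report$seed, stages = report$stages,
         n_records = nrow(report$trial$records)),
    file.path(outdir, "MANIFEST.json"), auto_unbox = TRUE)
  invisible(outdir)
}

#' Write simulated trial tables as delimited text
#'
#' @param trial a `peach_trial`.
#' @param outdir output directory.
#' @return `outdir`, invisibly.
#' @export
write_trial <- function(trial, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(trial$records, file.path(outdir, "trial_records.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(trial$foliar, file.path(outdir, "foliar.csv"),
                   row.names = FALSE, quote = FALSE)
  if (!is.null(trial$weather)) {
    utils::write.csv(trial$weather$daily,
                     file.path(outdir, "weather_daily.csv"),
                     row.names = FALSE, quote = FALSE)
    utils::write.csv(trial$weather$hourly,
                     file.path(outdir, "weather_hourly.csv"),
                     row.names = FALSE, quote = FALSE)
  }
  invisible(outdir)
}

#' Read a trial back from delimited-text files
#'
#' Counterpart of [write_trial()] for externally supplied records.
#'
#' @param records_path,foliar_path CSV paths.
#' @param daily_path,hourly_path optional weather CSV paths.
#' @return list with `records`, `foliar` and optionally `weather`.
#' @export
read_trial <- function(records_path, foliar_path, daily_path = NULL,
                       hourly_path = NULL) {
  out <- list(records = utils::read.csv(records_path,
                                        stringsAsFactors = FALSE),
              foliar = read_foliar(foliar_path))
  if (!is.null(daily_path))
    out$weather <- read_weather(daily_path, hourly_path)
  out
}
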