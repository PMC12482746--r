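#' Run the full external-validation study end-to-end
#'
#' Orchestrates the whole workflow on a synthetic cohort: generate ->
#' mask labs -> label outcomes -> impute -> score both models -> map to
#' probabilities -> bootstrap validation metrics -> logistic recalibration
#' -> re-validation -> Gupta risk stratification -> decision curve
#' analysis -> magnesium-exclusion sensitivity AUROC comparison.
#' Deterministic per (config, seed). With `out_dir` set, every
#' intermediate is written as plain CSV/TSV/JSON together with a run
#' manifest, so any stage can be re-run from saved intermediates.
#'
#' @param config A `caki_config`. Default [default_config()].
#' @param seed Master seed; stage seeds are derived from it.
#' @param n_boot Bootstrap replicates for the metric estimates.
#' @param out_dir Optional output directory for artifact files.
#' @param boot_refit Refit the recalibration inside each bootstrap
#'   replicate (`TRUE`) or bootstrap the once-fitted recalibrated
#'   probabilities (default `FALSE`, the apparent-validation reading).
#' @return Object of class `caki_study` with elements `cohort` (scored,
#'   labelled data frame), `truth`, `report` (per model x outcome x
#'   pre/post metric estimates), `auroc_comparisons`, `stratification`,
#'   `dca` (per outcome), `recalibrations`, `mapper`,
#'   `magnesium_sensitivity`, `manifest`.
#' @export
run_validation_study <- function(config = default_config(),
                                 seed = config$seed, n_boot = 1000,
                                 out_dir = NULL, boot_refit = FALSE) {
  t0 <- Sys.time()
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop("[stage: ", what, "] ", conditionMessage(e), call. = FALSE))
  }
  sim <- stage("simulate", generate_cohort(config, seed = seed))
  coh <- stage("missingness",
               apply_missingness(sim$cohort, config, seed = seed + 1L))
  coh <- stage("label", label_cohort(coh))
  imputer <- stage("impute", fit_imputer(coh))
  coh <- stage("impute", impute(coh, imputer))

  coh$motwani_points <- stage("score",
    motwani_score(coh$age, coh$hypertension, coh$cddp_dose, coh$albumin))
  coh$gupta_points <- stage("score",
    gupta_score(coh$age, coh$hypertension, coh$diabetes, coh$smoker,
                coh$cddp_dose, coh$hemoglobin, coh$wbc, coh$albumin,
                coh$magnesium))
  coh$gupta_points_no_mg <- stage("score",
    gupta_score(coh$age, coh$hypertension, coh$diabetes, coh$smoker,
                coh$cddp_dose, coh$hemoglobin, coh$wbc, coh$albumin,
                include_magnesium = FALSE))
  coh$gupta_risk_group <- as.character(gupta_risk_group(coh$gupta_points))
  coh$motwani_probability <- motwani_probability(coh$motwani_points)
  # reference-cohort fit of the spline mapper: the severe outcome, which
  # the Gupta model was developed against
  mapper <- stage("score", fit_gupta_mapper(coh$gupta_points,
                                            coh$severe_caki))
  coh$gupta_probability <- gupta_probability(coh$gupta_points, mapper)

  outcomes <- list(caki = coh$caki, severe_caki = coh$severe_caki)
  models <- list(
    motwani = list(points = coh$motwani_points,
                   probability = coh$motwani_probability),
    gupta = list(points = coh$gupta_points,
                 probability = coh$gupta_probability))
  report <- list(); recals <- list()
  bseed <- seed + 100L
  for (oc in names(outcomes)) {
    y <- outcomes[[oc]]
    for (md in names(models)) {
      pts <- models[[md]]$points
      p_pre <- models[[md]]$probability
      rec <- stage("recalibrate",
                   logistic_recalibrate(pts, y, model = md))
      recals[[paste(md, oc, sep = ".")]] <- rec
      p_post <- apply_recalibration(rec, pts)
      refit_fun <- if (boot_refit) {
        function(p, yy) {
          s <- (stats::qlogis(p) - rec$intercept) / rec$slope_per_point
          apply_recalibration(logistic_recalibrate(s, yy, model = md), s)
        }
      } else NULL
      report[[paste(md, oc, "pre", sep = ".")]] <- stage("validate",
        bootstrap_metrics(p_pre, y, n_boot = n_boot, seed = bseed))
      report[[paste(md, oc, "post", sep = ".")]] <- stage("validate",
        bootstrap_metrics(p_post, y, n_boot = n_boot, seed = bseed + 1L,
                          refit = refit_fun))
      bseed <- bseed + 10L
    }
  }
  comparisons <- lapply(outcomes, function(y)
    stage("validate", compare_auroc(models$gupta$points,
                                    models$motwani$points, y,
                                    n_boot = n_boot, seed = bseed)))
  mg_sens <- stage("validate",
    compare_auroc(coh$gupta_points, coh$gupta_points_no_mg,
                  coh$severe_caki, n_boot = n_boot, seed = bseed + 1L))

  strat <- stage("stratify", stratification_table(coh))
  dca <- list(
    caki = stage("dca", decision_curve(
      list(motwani = coh$motwani_probability,
           motwani_recal = apply_recalibration(recals$motwani.caki,
                                               coh$motwani_points),
           gupta = coh$gupta_probability,
           gupta_recal = apply_recalibration(recals$gupta.caki,
                                             coh$gupta_points)),
      coh$caki)),
    severe_caki = stage("dca", decision_curve(
      list(motwani = coh$motwani_probability,
           motwani_recal = apply_recalibration(recals$motwani.severe_caki,
                                               coh$motwani_points),
           gupta = coh$gupta_probability,
           gupta_recal = apply_recalibration(recals$gupta.severe_caki,
                                             coh$gupta_points)),
      coh$severe_caki)))

  manifest <- list(package_version = as.character(
                     utils::packageVersion("cakival")),
                   seed = seed, n_boot = n_boot,
                   n_patients = nrow(coh),
                   events = vapply(outcomes, sum, numeric(1)),
                   boot_refit = boot_refit,
                   started = format(t0, "%Y-%m-%dT%H:%M:%S"),
                   out_dir = if (is.null(out_dir)) NA else out_dir)
  study <- structure(list(cohort = coh, truth = sim$truth, report = report,
                          auroc_comparisons = comparisons,
                          stratification = strat, dca = dca,
                          recalibrations = recals, mapper = mapper,
                          imputer = imputer,
                          magnesium_sensitivity = mg_sens,
                          manifest = manifest, config = config),
                     class = "caki_study")
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

#' Gupta risk-stratification table
#'
#' Per risk group: patient count, severe C-AKI events and observed
#' incidence; row counts sum to the cohort size, events to the total.
#'
#' @param cohort Scored, labelled cohort (needs `gupta_risk_group` and
#'   `severe_caki` columns).
#' @return Data frame with one row per risk group.
#' @export
stratification_table <- function(cohort) {
  grp <- factor(cohort$gupta_risk_group,
                levels = c("low", "moderate", "high", "very_high"))
  do.call(rbind, lapply(levels(grp), function(g) {
    i <- grp == g
    data.frame(risk_group = g, n = sum(i),
               severe_events = sum(cohort$severe_caki[i]),
               incidence = if (any(i)) mean(cohort$severe_caki[i]) else NA_real_)
  }))
}

#' Flatten the study report into a Table-3-style data frame
#'
#' One row per model x outcome x pre/post x metric with bootstrap mean and
#' 95% CI: 4 metrics x 2 models x 2 outcomes x 2 phases = 32 rows.
#'
#' @param study A `caki_study`.
#' @return Data frame.
#' @export
report_table <- function(study) {
  rows <- lapply(names(study$report), function(key) {
    parts <- strsplit(key, ".", fixed = TRUE)[[1]]
    est <- study$report[[key]]
    data.frame(model = parts[1], outcome = parts[2], phase = parts[3],
               metric = est$metric, point = est$point,
               ci_low = est$ci_low, ci_high = est$ci_high)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write all study artifacts to a directory
#'
#' Plain-text artifact set: cohort CSV (scored + labelled), long
#' trajectories CSV, truth CSV, Table-3-layout TSV, stratification CSV,
#' decision-curve CSVs, recalibration/mapper/imputer JSON and the run
#' manifest JSON.
#'
#' @param study A `caki_study`.
#' @param out_dir Directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_study <- function(study, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(...) file.path(out_dir, ...)
  write_cohort_csv(study$cohort, fp("cohort.csv"))
  utils::write.csv(trajectories_long(study$cohort), fp("trajectories.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(study$truth, fp("truth.csv"), row.names = FALSE,
                   quote = FALSE)
  tab <- report_table(study)
  utils::write.table(tab, fp("validation_report.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  utils::write.csv(study$stratification, fp("stratification.csv"),
                   row.names = FALSE, quote = FALSE)
  for (oc in names(study$dca))
    utils::write.csv(as.data.frame(study$dca[[oc]]),
                     fp(sprintf("decision_curve_%s.csv", oc)),
                     row.names = FALSE, quote = FALSE)
  recal_js <- lapply(study$recalibrations, unclass)
  writeLines(jsonlite::toJSON(list(
    recalibrations = recal_js,
    auroc_comparisons = study$auroc_comparisons,
    magnesium_sensitivity = study$magnesium_sensitivity,
    manifest = study$manifest), auto_unbox = TRUE, digits = NA,
    na = "null"), fp("report.json"))
  mapper_to_json(study$mapper, fp("gupta_mapper.json"))
  imputer_to_json(study$imputer, fp("imputer.json"))
  invisible(out_dir)
}

#' @export
print.caki_study <- function(x, ...) {
  m <- x$manifest
  cat(sprintf("C-AKI external-validation study (synthetic cohort, n = %d, seed = %d)\n",
              m$n_patients, m$seed))
  cat(sprintf("  events: C-AKI %d (%.1f%%), severe %d (%.1f%%)\n",
              m$events[["caki"]], 100 * m$events[["caki"]] / m$n_patients,
              m$events[["severe_caki"]],
              100 * m$events[["severe_caki"]] / m$n_patients))
  tab <- report_table(x)
  au <- tab[tab$metric == "auroc" & tab$phase == "pre", ]
  for (i in seq_len(nrow(au)))
    cat(sprintf("  AUROC %-8s %-12s %.3f (%.3f-%.3f)\n", au$model[i],
                au$outcome[i], au$point[i], au$ci_low[i], au$ci_high[i]))
  invisible(x)
}

#' @export
summary.caki_study <- function(object, ...) {
  print(object)
  cat("\nValidation metrics (bootstrap mean, 95% CI):\n")
  tab <- report_table(object)
  tab$estimate <- sprintf("%.3f (%.3f-%.3f)", tab$point, tab$ci_low,
                          tab$ci_high)
  print(tab[, c("model", "outcome", "phase", "metric", "estimate")],
        row.names = FALSE)
  cat("\nGupta risk stratification (severe C-AKI):\n")
  print(object$stratification, row.names = FALSE, digits = 3)
  for (oc in names(object$auroc_comparisons)) {
    cmp <- object$auroc_comparisons[[oc]]
    cat(sprintf("\nGupta vs Motwani AUROC, %s: delta %.3f (%.3f-%.3f), p = %.3g\n",
                oc, cmp$delta, cmp$ci_low, cmp$ci_high, cmp$p_value))
  }
  mg <- object$magnesium_sensitivity
  cat(sprintf("Magnesium exclusion (severe): delta AUROC %.3f (%.3f-%.3f), p = %.3g\n",
              mg$delta, mg$ci_low, mg$ci_high, mg$p_value))
  invisible(object)
}
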