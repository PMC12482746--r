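#' Label C-AKI outcomes from a creatinine trajectory
#'
#' Applies the KDIGO-anchored study definitions to one patient's
#' post-cisplatin serum-creatinine series. C-AKI is an absolute rise of at
#' least 0.3 mg/dL from baseline or a 1.5-fold or greater rise, within the
#' assessment window (default 14 days). Severe C-AKI is a 2.0-fold or
#' greater rise, or the initiation of renal replacement therapy (RRT)
#' within the window, regardless of creatinine. All threshold comparisons
#' are inclusive; a ratio of exactly 2.0 is severe. Only trajectory points
#' with `day <= window_days` count; day 0 is baseline, post-exposure days
#' start at 1.
#'
#' Note the 0.3 mg/dL criterion is applied over the whole window rather
#' than the strict 48-hour KDIGO reading, matching how the Motwani model's
#' outcome is defined.
#'
#' @param baseline Baseline serum creatinine, mg/dL (> 0).
#' @param days Integer vector of post-exposure day offsets (1..window).
#' @param values Creatinine values (mg/dL) matching `days`.
#' @param rrt Logical; RRT initiated within the window.
#' @param window_days Assessment window in days. Default 14.
#' @return A list of class `caki_labels`: `caki`, `severe_caki` (logical),
#'   `stage` (factor: `none`, `stage1`, `stage2plus`), `max_post_creatinine`
#'   and `fold_change` (NA when no in-window point exists).
#' @export
label_outcomes <- function(baseline, days, values, rrt = FALSE,
                           window_days = 14) {
  if (is.na(baseline) || baseline <= 0)
    stop("baseline creatinine must be present and > 0", call. = FALSE)
  if (length(days) != length(values))
    stop("days and values differ in length", call. = FALSE)
  keep <- !is.na(values) & days >= 1 & days <= window_days
  if (!any(keep) && !isTRUE(rrt)) {
    stop(structure(class = c("caki_unassessable", "error", "condition"),
         list(message = paste0("outcome unassessable: no creatinine value ",
                               "within ", window_days, " days and no RRT"),
              call = NULL)))
  }
  if (any(keep)) {
    max_post <- max(values[keep])
    fold <- max_post / baseline
    delta <- max_post - baseline
  } else {
    max_post <- NA_real_; fold <- NA_real_; delta <- -Inf
  }
  # inclusive thresholds with a 1e-9 tolerance so values that are exactly
  # on a printed decimal boundary (e.g. 0.6/0.4 = 1.5) classify positive
  # despite binary floating point
  tol <- 1e-9
  severe <- isTRUE(rrt) || (is.finite(fold) && fold >= 2.0 - tol)
  caki <- severe || delta >= 0.3 - tol ||
    (is.finite(fold) && fold >= 1.5 - tol)
  stage <- if (severe) "stage2plus" else if (caki) "stage1" else "none"
  structure(list(caki = caki, severe_caki = severe,
                 stage = factor(stage,
                                levels = c("none", "stage1", "stage2plus")),
                 max_post_creatinine = max_post, fold_change = fold),
            class = "caki_labels")
}

#' @export
print.caki_labels <- function(x, ...) {
  cat("C-AKI:", x$caki, " severe:", x$severe_caki,
      " stage:", as.character(x$stage), "\n")
  if (!is.na(x$fold_change))
    cat(sprintf("  peak creatinine %.2f mg/dL (%.2f-fold)\n",
                x$max_post_creatinine, x$fold_change))
  invisible(x)
}

#' Label an entire cohort
#'
#' Vectorised wrapper around [label_outcomes()] for a cohort data frame as
#' produced by [generate_cohort()] or [read_cohort_csv()]. Trajectories are
#' taken from the `trajectory` column (serialised `day:value;day:value`
#' pairs) or from a long-format companion data frame.
#'
#' @param cohort Cohort data frame with `baseline_creatinine`,
#'   `rrt_within_window` and either a `trajectory` column or `trajectories`.
#' @param trajectories Optional long-format data frame with columns
#'   `patient_id`, `day`, `creatinine_mg_dl`.
#' @param window_days Assessment window in days.
#' @return The cohort with columns `caki`, `severe_caki`, `stage`,
#'   `max_post_creatinine`, `fold_change` appended.
#' @export
label_cohort <- function(cohort, trajectories = NULL, window_days = 14) {
  n <- nrow(cohort)
  traj <- if (is.null(trajectories)) {
    lapply(cohort$trajectory, parse_trajectory)
  } else {
    idx <- split(seq_len(nrow(trajectories)), trajectories$patient_id)
    lapply(cohort$patient_id, function(id) {
      i <- idx[[id]]
      if (is.null(i)) data.frame(day = integer(0), value = numeric(0))
      else data.frame(day = trajectories$day[i],
                      value = trajectories$creatinine_mg_dl[i])
    })
  }
  lab <- vector("list", n)
  for (i in seq_len(n)) {
    lab[[i]] <- label_outcomes(cohort$baseline_creatinine[i],
                               traj[[i]]$day, traj[[i]]$value,
                               rrt = cohort$rrt_within_window[i],
                               window_days = window_days)
  }
  cohort$caki <- vapply(lab, `[[`, logical(1), "caki")
  cohort$severe_caki <- vapply(lab, `[[`, logical(1), "severe_caki")
  cohort$stage <- vapply(lab, function(l) as.character(l$stage), character(1))
  cohort$max_post_creatinine <- vapply(lab, `[[`, numeric(1),
                                       "max_post_creatinine")
  cohort$fold_change <- vapply(lab, `[[`, numeric(1), "fold_change")
  cohort
}

#' Parse a serialised trajectory string
#'
#' Trajectories travel in the cohort CSV as `day:value` pairs joined by
#' semicolons, e.g. `"3:0.81;7:1.02;14:0.90"`.
#'
#' @param x A single trajectory string (may be empty or NA).
#' @return Data frame with columns `day` and `value`.
#' @export
parse_trajectory <- function(x) {
  if (is.na(x) || !nzchar(x))
    return(data.frame(day = integer(0), value = numeric(0)))
  parts <- strsplit(strsplit(x, ";", fixed = TRUE)[[1]], ":", fixed = TRUE)
  data.frame(day = as.integer(vapply(parts, `[[`, character(1), 1)),
             value = as.numeric(vapply(parts, `[[`, character(1), 2)))
}

#' Serialise a trajectory to its CSV string form
#' @param day Integer day offsets.
#' @param value Creatinine values (mg/dL).
#' @return A single string of `day:value` pairs.
#' @export
format_trajectory <- function(day, value) {
  if (!length(day)) return("")
  paste(sprintf("%d:%s", as.integer(day),
                formatC(value, digits = 6, format = "fg")), collapse = ";")
}
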