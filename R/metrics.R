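#' Area under the ROC curve
#'
#' Concordance (Mann-Whitney) estimator: the probability that a randomly
#' chosen event patient receives a higher prediction than a randomly chosen
#' non-event patient, with ties credited 0.5. Invariant to any strictly
#' increasing transform of the predictions, so raw scores and mapped
#' probabilities give identical values.
#'
#' @param predictions Numeric predictions (scores or probabilities).
#' @param outcomes Binary outcomes (0/1 or logical).
#' @return AUROC in [0, 1].
#' @export
auroc <- function(predictions, outcomes) {
  y <- .as_binary(outcomes)
  if (anyNA(predictions) || any(!is.finite(predictions)))
    stop("predictions must be finite", call. = FALSE)
  n1 <- sum(y == 1L); n0 <- sum(y == 0L)
  if (n1 == 0L || n0 == 0L)
    stop("AUROC undefined: outcomes contain a single class", call. = FALSE)
  r <- rank(predictions, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

.clip_prob <- function(p, eps = 1e-9) {
  if (anyNA(p)) stop("probabilities contain NA", call. = FALSE)
  if (any(p < 0) || any(p > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (any(p <= 0) || any(p >= 1)) {
    warning("probabilities at 0/1 clipped to [", format(eps), ", 1 - ",
            format(eps), "] before logit", call. = FALSE)
    p <- pmin(pmax(p, eps), 1 - eps)
  }
  p
}

#' Calibration-in-the-large
#'
#' Intercept of a maximum-likelihood logistic regression of the outcome on
#' the logit of the predicted probability with the slope fixed at 1 (offset
#' formulation). 0 is ideal; negative values indicate systematic
#' overestimation of risk, positive values underestimation.
#'
#' @param probabilities Predicted probabilities in (0, 1); values at the
#'   boundary are clipped at 1e-9 with a warning.
#' @param outcomes Binary outcomes.
#' @return The intercept (logit scale).
#' @export
citl <- function(probabilities, outcomes) {
  y <- .as_binary(outcomes)
  lp <- stats::qlogis(.clip_prob(probabilities))
  fit <- stats::glm(y ~ 1 + offset(lp), family = stats::binomial())
  if (!fit$converged)
    stop("calibration-in-the-large fit did not converge (",
         fit$iter, " iterations)", call. = FALSE)
  unname(stats::coef(fit)[1])
}

#' Calibration slope
#'
#' Coefficient of the logit of predicted probability in an unconstrained
#' logistic refit of the outcome. 1 is ideal; values below 1 indicate
#' predictions that are too extreme, values above 1 predictions that are
#' too timid.
#'
#' @inheritParams citl
#' @return The slope coefficient.
#' @export
calibration_slope <- function(probabilities, outcomes) {
  y <- .as_binary(outcomes)
  lp <- stats::qlogis(.clip_prob(probabilities))
  if (stats::var(lp) == 0)
    stop("calibration slope undefined: predictions have zero variance",
         call. = FALSE)
  fit <- stats::glm(y ~ lp, family = stats::binomial())
  unname(stats::coef(fit)["lp"])
}

#' Brier score
#'
#' Mean squared difference between predicted probability and the binary
#' outcome; 0 is ideal. A constant prediction at the event prevalence pi
#' has expectation pi * (1 - pi).
#'
#' @inheritParams citl
#' @return The Brier score in [0, 1].
#' @export
brier <- function(probabilities, outcomes) {
  y <- .as_binary(outcomes)
  if (any(probabilities < 0) || any(probabilities > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  mean((probabilities - y)^2)
}

.metric_funs <- list(auroc = function(p, y) auroc(p, y),
                     citl = function(p, y) citl(p, y),
                     slope = function(p, y) calibration_slope(p, y),
                     brier = function(p, y) brier(p, y))

#' Bootstrap validation metrics
#'
#' Resamples patients with replacement and recomputes AUROC,
#' calibration-in-the-large, calibration slope and Brier score on each
#' replicate, reporting the bootstrap mean and percentile 2.5/97.5 bounds
#' for each (the Table-3-style presentation). Replicates whose resampled
#' outcome is single-class are redrawn and counted.
#'
#' @inheritParams citl
#' @param n_boot Number of bootstrap replicates. Default 1000.
#' @param seed Integer seed for the resampling.
#' @param refit Optional function `(probabilities, outcomes) -> probabilities`
#'   applied inside every replicate before the metrics are computed; used
#'   for honest post-recalibration bootstraps where the recalibration is
#'   refit per replicate. Default `NULL` (metrics on the supplied
#'   probabilities as-is).
#' @return Object of class `caki_metrics`: a data frame with one row per
#'   metric (`point` = bootstrap mean, `ci_low`, `ci_high`) plus the
#'   full-sample estimates as attribute `observed` and bookkeeping fields.
#' @export
bootstrap_metrics <- function(probabilities, outcomes, n_boot = 1000,
                              seed = 1L, refit = NULL) {
  y <- .as_binary(outcomes)
  if (n_boot < 2) stop("n_boot must be at least 2", call. = FALSE)
  if (sum(y) < 2 || sum(1 - y) < 2)
    stop("bootstrap refused: fewer than 2 events or 2 non-events",
         call. = FALSE)
  n <- length(y)
  reps <- matrix(NA_real_, n_boot, 4,
                 dimnames = list(NULL, names(.metric_funs)))
  redraws <- 0L
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2L) break
      redraws <- redraws + 1L
    }
    pb <- probabilities[idx]; yb <- y[idx]
    if (!is.null(refit)) pb <- refit(pb, yb)
    reps[b, ] <- suppressWarnings(vapply(.metric_funs, function(f)
      tryCatch(f(pb, yb), error = function(e) NA_real_), numeric(1)))
  }
  est <- data.frame(
    metric = colnames(reps),
    point = colMeans(reps, na.rm = TRUE),
    ci_low = apply(reps, 2, stats::quantile, 0.025, na.rm = TRUE,
                   names = FALSE),
    ci_high = apply(reps, 2, stats::quantile, 0.975, na.rm = TRUE,
                    names = FALSE),
    row.names = NULL)
  observed <- suppressWarnings(vapply(.metric_funs, function(f)
    tryCatch(f(probabilities, y), error = function(e) NA_real_), numeric(1)))
  structure(est, observed = observed, n = n, events = sum(y),
            n_boot = n_boot, seed = seed, redraws = redraws,
            class = c("caki_metrics", "data.frame"))
}

#' @export
print.caki_metrics <- function(x, digits = 3, ...) {
  cat(sprintf("Bootstrap validation metrics (n = %d, events = %d, %d replicates)\n",
              attr(x, "n"), attr(x, "events"), attr(x, "n_boot")))
  df <- data.frame(metric = x$metric,
                   estimate = sprintf(paste0("%.", digits, "f (%.", digits,
                                             "f-%.", digits, "f)"),
                                      x$point, x$ci_low, x$ci_high))
  print(df, row.names = FALSE)
  if (attr(x, "redraws") > 0)
    cat(attr(x, "redraws"), "single-class replicate(s) redrawn\n")
  invisible(x)
}

#' Bootstrap comparison of two AUROCs
#'
#' Paired patient-level bootstrap of the AUROC difference between two
#' prediction vectors on the same patients. The two-sided p-value is
#' `2 * min(P(delta <= 0), P(delta >= 0))`, floored at `1 / n_boot`, with a
#' percentile CI for the difference.
#'
#' @param predictions_a,predictions_b Predictions for the same patients.
#' @param outcomes Binary outcomes.
#' @inheritParams bootstrap_metrics
#' @return List: `delta` (observed AUROC difference a - b), `ci_low`,
#'   `ci_high`, `p_value`, `n_boot`.
#' @export
compare_auroc <- function(predictions_a, predictions_b, outcomes,
                          n_boot = 1000, seed = 1L) {
  y <- .as_binary(outcomes)
  if (length(predictions_a) != length(predictions_b) ||
      length(predictions_a) != length(y))
    stop("prediction vectors and outcomes must cover the same patients",
         call. = FALSE)
  if (sum(y) < 2 || sum(1 - y) < 2)
    stop("bootstrap refused: fewer than 2 events or 2 non-events",
         call. = FALSE)
  n <- length(y)
  old <- .save_seed(); on.exit(.restore_seed(old))
  set.seed(seed)
  delta_b <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) == 2L) break
    }
    delta_b[b] <- auroc(predictions_a[idx], y[idx]) -
                  auroc(predictions_b[idx], y[idx])
  }
  p <- 2 * min(mean(delta_b <= 0), mean(delta_b >= 0))
  list(delta = auroc(predictions_a, y) - auroc(predictions_b, y),
       ci_low = stats::quantile(delta_b, 0.025, names = FALSE),
       ci_high = stats::quantile(delta_b, 0.975, names = FALSE),
       p_value = max(min(p, 1), 1 / n_boot),
       n_boot = n_boot)
}

#' Decile calibration curve
#'
#' Splits the cohort into risk-based groups by deciles of predicted
#' probability (equal-count, ties kept together) and reports per-bin mean
#' prediction, observed event rate and counts, plus a loess-smoothed
#' observed-vs-predicted curve (span 0.75) over the prediction range.
#'
#' @inheritParams citl
#' @param n_bins Number of risk groups. Default 10.
#' @return List of class `caki_calibration`: `bins` (data frame), `smooth`
#'   (data frame with `p` and `observed`), `n`, `events`.
#' @export
calibration_curve <- function(probabilities, outcomes, n_bins = 10) {
  y <- .as_binary(outcomes)
  n <- length(y)
  if (n < n_bins) stop("need at least n_bins patients", call. = FALSE)
  qs <- stats::quantile(probabilities, probs = seq(0, 1, length.out = n_bins + 1),
                        names = FALSE)
  edges <- unique(qs)
  if (length(edges) - 1 < n_bins)
    warning("fewer distinct predictions than bins; bins merged",
            call. = FALSE)
  if (length(edges) == 1L) {
    bin <- rep(1L, n)
  } else {
    bin <- cut(probabilities, breaks = edges, include.lowest = TRUE,
               labels = FALSE)
  }
  bins <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    i <- bin == b
    data.frame(bin = b, n = sum(i), events = sum(y[i]),
               mean_predicted = mean(probabilities[i]),
               observed_rate = mean(y[i]))
  }))
  smooth <- tryCatch(suppressWarnings({
    fit <- stats::loess(y ~ probabilities, span = 0.75,
                        degree = 1, family = "gaussian")
    grid <- seq(min(probabilities), max(probabilities), length.out = 100)
    data.frame(p = grid,
               observed = pmin(pmax(stats::predict(fit, grid), 0), 1))
  }), error = function(e) data.frame(p = numeric(0), observed = numeric(0)))
  structure(list(bins = bins, smooth = smooth, n = n, events = sum(y)),
            class = "caki_calibration")
}

#' @export
print.caki_calibration <- function(x, ...) {
  cat("Calibration curve:", nrow(x$bins), "risk groups, n =", x$n,
      "with", x$events, "events\n")
  print(x$bins, row.names = FALSE, digits = 3)
  invisible(x)
}

#' @export
plot.caki_calibration <- function(x, ...) {
  graphics::plot(x$bins$mean_predicted, x$bins$observed_rate,
                 xlab = "Predicted probability", ylab = "Observed rate",
                 pch = 2, xlim = c(0, max(x$bins$mean_predicted, 0.2)),
                 ylim = c(0, max(x$bins$observed_rate, 0.2)), ...)
  graphics::abline(0, 1, col = "red")
  if (nrow(x$smooth)) graphics::lines(x$smooth$p, x$smooth$observed)
  invisible(x)
}

# Preserve the caller's RNG state across seeded internals.
.save_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}
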