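#' Logistic recalibration of a risk score
#'
#' Re-estimates only an intercept and a slope for an existing score in a
#' new population: a maximum-likelihood logistic regression with the
#' outcome as the dependent variable and the raw score as the independent
#' variable. No structural update is performed — exactly two parameters are
#' fitted. Recalibration cannot change discrimination (the mapping is
#' strictly monotone for positive slope), but it repairs
#' calibration-in-the-large and the calibration slope on the cohort it was
#' fitted to.
#'
#' @param scores Raw score points.
#' @param outcomes Binary outcomes.
#' @param model Optional label carried in the result (e.g. `"motwani"`).
#' @return Object of class `caki_recal` with `coef()`, `predict()`,
#'   `print()` support: `intercept`, `slope_per_point` (logit units per
#'   score point), `n`, `events`, `converged`.
#' @export
logistic_recalibrate <- function(scores, outcomes, model = "score") {
  y <- .as_binary(outcomes)
  if (length(scores) != length(y))
    stop("scores and outcomes differ in length", call. = FALSE)
  events <- sum(y); nonevents <- sum(1 - y)
  if (events < 2 || nonevents < 2)
    stop("recalibration refused: fewer than 2 events or 2 non-events",
         call. = FALSE)
  if (events < 10 || nonevents < 10)
    warning("recalibration with fewer than 10 events or non-events ",
            "(", events, " events); estimates may be unstable",
            call. = FALSE)
  if (stats::var(scores) == 0)
    stop("recalibration degenerate: all scores equal", call. = FALSE)
  fit <- suppressWarnings(
    stats::glm(y ~ scores, family = stats::binomial()))
  p <- stats::fitted(fit)
  if (any(p > 1 - 1e-8) || any(p < 1e-8))
    stop("recalibration failed: separation detected (fitted probabilities ",
         "at 0/1)", call. = FALSE)
  if (!fit$converged)
    stop("recalibration did not converge after ", fit$iter, " iterations",
         call. = FALSE)
  cf <- unname(stats::coef(fit))
  structure(list(model = model, intercept = cf[1], slope_per_point = cf[2],
                 n = length(y), events = events,
                 converged = fit$converged, iterations = fit$iter),
            class = "caki_recal")
}

#' @export
coef.caki_recal <- function(object, ...) {
  c(intercept = object$intercept, slope_per_point = object$slope_per_point)
}

#' @export
print.caki_recal <- function(x, ...) {
  cat(sprintf("Logistic recalibration of the %s score\n", x$model))
  cat(sprintf("  intercept %.4f, slope %.4f per point (n = %d, events = %d)\n",
              x$intercept, x$slope_per_point, x$n, x$events))
  invisible(x)
}

#' @export
predict.caki_recal <- function(object, newdata, ...) {
  apply_recalibration(object, newdata)
}

#' Apply recalibration parameters to scores
#'
#' Maps raw score points to recalibrated probabilities
#' `plogis(intercept + slope * score)`; strictly increasing in the score
#' when the slope is positive.
#'
#' @param params A `caki_recal` object (or list with `intercept` and
#'   `slope_per_point`).
#' @param scores Raw score points.
#' @return Recalibrated probabilities.
#' @export
apply_recalibration <- function(params, scores) {
  stats::plogis(params$intercept + params$slope_per_point * scores)
}

#' Export recalibration parameters to JSON
#' @param params A `caki_recal`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return JSON string (invisibly when written).
#' @export
recal_to_json <- function(params, path = NULL) {
  stopifnot(inherits(params, "caki_recal"))
  js <- jsonlite::toJSON(unclass(params), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read recalibration parameters from JSON
#' @param path File written by [recal_to_json()].
#' @return A `caki_recal`.
#' @export
recal_from_json <- function(path) {
  structure(jsonlite::fromJSON(path), class = "caki_recal")
}
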