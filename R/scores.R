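#' Motwani C-AKI risk score
#'
#' Computes the points-based Motwani score for cisplatin-associated acute
#' kidney injury (any C-AKI: creatinine rise of at least 0.3 mg/dL within
#' 14 days). Four predictors contribute points: age (<= 60: 0; 61-70: 1.5;
#' > 70: 2.5), hypertension (2), cisplatin dose in mg (<= 100: 0;
#' 101-150: 1; > 150: 3) and serum albumin in g/dL (> 3.5: 0; <= 3.5: 2).
#' The total lies on a half-point grid in [0, 10].
#'
#' @param age Age in years (numeric vector).
#' @param hypertension Logical vector; treated hypertension.
#' @param cddp_dose Cisplatin dose in mg.
#' @param albumin Serum albumin in g/dL (must be imputed/observed, not NA).
#' @return Numeric vector of score points (multiples of 0.5, range 0-10).
#' @seealso [gupta_score()], [motwani_probability()]
#' @examples
#' motwani_score(age = 65, hypertension = TRUE, cddp_dose = 120, albumin = 3.4)
#' @export
motwani_score <- function(age, hypertension, cddp_dose, albumin) {
  .check_score_inputs(list(age = age, hypertension = hypertension,
                           cddp_dose = cddp_dose, albumin = albumin))
  pts_age  <- ifelse(age <= 60, 0, ifelse(age <= 70, 1.5, 2.5))
  pts_htn  <- ifelse(hypertension, 2, 0)
  pts_dose <- ifelse(cddp_dose <= 100, 0, ifelse(cddp_dose <= 150, 1, 3))
  pts_alb  <- ifelse(albumin > 3.5, 0, 2)
  pts_age + pts_htn + pts_dose + pts_alb
}

#' Gupta simple-model C-AKI risk score
#'
#' Computes the points-based Gupta simple score (developed against severe
#' C-AKI: >= 2.0-fold creatinine rise or RRT within 14 days). Contributions:
#' age (<= 45: 0; 46-60: 2.5; 61-70: 3.5; > 70: 4.5), hypertension (1),
#' diabetes (1), current smoking (1), cisplatin dose in mg (<= 50: 0;
#' 51-75: 2; 76-100: 2.5; 101-125: 3; 126-150: 5; 151-200: 7.5; > 200: 9.5),
#' hemoglobin in g/dL (>= 12.0: 0; 11.0-11.9: 1; < 11.0: 1.5), white blood
#' cells in 10^3/mm^3 (<= 12.0: 0; > 12.0: 1.5), albumin in g/dL
#' (> 3.8: 0; 3.3-3.8: 1; < 3.3: 1.5) and magnesium in mg/dL (>= 2.0: 0;
#' < 2.0: 1). Continuous predictors bin with the printed edges; a value
#' strictly between two printed edges (e.g. dose 100.5, hemoglobin 11.95)
#' joins the bin of the next printed upper edge, i.e. ranges such as
#' "101-150" are read as (100, 150]. The total lies on a half-point grid in
#' [0, 22.5] (21.5 without magnesium).
#'
#' Albumin and hemoglobin are taken in g/dL: the published point table
#' labels them mg/dL, but the companion cohort tables and clinical ranges
#' make clear g/dL is meant.
#'
#' @param age Age in years.
#' @param hypertension,diabetes,smoker Logical vectors.
#' @param cddp_dose Cisplatin dose in mg.
#' @param hemoglobin Hemoglobin in g/dL.
#' @param wbc White blood cell count in 10^3/mm^3.
#' @param albumin Serum albumin in g/dL.
#' @param magnesium Serum magnesium in mg/dL. Ignored when
#'   `include_magnesium = FALSE` (the sensitivity variant).
#' @param include_magnesium Include the magnesium item? Default `TRUE`.
#' @return Numeric vector of score points.
#' @export
gupta_score <- function(age, hypertension, diabetes, smoker, cddp_dose,
                        hemoglobin, wbc, albumin, magnesium = NULL,
                        include_magnesium = TRUE) {
  req <- list(age = age, hypertension = hypertension, diabetes = diabetes,
              smoker = smoker, cddp_dose = cddp_dose, hemoglobin = hemoglobin,
              wbc = wbc, albumin = albumin)
  if (include_magnesium) req["magnesium"] <- list(magnesium)
  .check_score_inputs(req)
  pts_age  <- ifelse(age <= 45, 0,
              ifelse(age <= 60, 2.5, ifelse(age <= 70, 3.5, 4.5)))
  pts_dose <- ifelse(cddp_dose <= 50, 0,
              ifelse(cddp_dose <= 75, 2,
              ifelse(cddp_dose <= 100, 2.5,
              ifelse(cddp_dose <= 125, 3,
              ifelse(cddp_dose <= 150, 5,
              ifelse(cddp_dose <= 200, 7.5, 9.5))))))
  pts_hb   <- ifelse(hemoglobin >= 12, 0, ifelse(hemoglobin >= 11, 1, 1.5))
  pts_wbc  <- ifelse(wbc <= 12, 0, 1.5)
  pts_alb  <- ifelse(albumin > 3.8, 0, ifelse(albumin >= 3.3, 1, 1.5))
  total <- pts_age + hypertension + diabetes + smoker + pts_dose +
    pts_hb + pts_wbc + pts_alb
  if (include_magnesium) total <- total + ifelse(magnesium >= 2, 0, 1)
  total
}

.check_score_inputs <- function(fields) {
  missing_fields <- names(fields)[vapply(fields, function(x)
    is.null(x) || anyNA(x), logical(1))]
  if (length(missing_fields))
    stop("missing required score predictor(s): ",
         paste(missing_fields, collapse = ", "),
         " (impute baseline labs before scoring)", call. = FALSE)
  invisible(TRUE)
}

#' Gupta risk-stratification group
#'
#' Bins a Gupta simple-score total into the published risk groups:
#' low (0-5.5), moderate (6-9.5), high (10-15.5) and very high (>= 16).
#'
#' @param points Gupta score points; non-negative multiples of 0.5.
#' @return Factor with levels `low`, `moderate`, `high`, `very_high`.
#' @export
gupta_risk_group <- function(points) {
  if (anyNA(points) || any(points < 0))
    stop("points must be non-negative and non-missing", call. = FALSE)
  if (any(abs(points * 2 - round(points * 2)) > 1e-8))
    stop("points must lie on the half-point grid", call. = FALSE)
  grp <- ifelse(points <= 5.5, "low",
         ifelse(points <= 9.5, "moderate",
         ifelse(points <= 15.5, "high", "very_high")))
  factor(grp, levels = c("low", "moderate", "high", "very_high"))
}

#' Motwani score-to-probability mapping
#'
#' Maps a Motwani score to a predicted C-AKI probability using the
#' development-cohort constants: incidence 0.04 at a score of 0 and an odds
#' ratio of 1.49 per one-point increase, i.e.
#' `odds(s) = (0.04 / 0.96) * 1.49^s` and `p = odds / (1 + odds)`.
#'
#' @param points Score points (non-negative).
#' @param p0 Baseline probability at score 0. Default 0.04.
#' @param or_per_point Odds ratio per point. Default 1.49.
#' @return Predicted probabilities, strictly increasing in `points`.
#' @export
motwani_probability <- function(points, p0 = 0.04, or_per_point = 1.49) {
  if (anyNA(points) || any(points < 0))
    stop("points must be non-negative and non-missing", call. = FALSE)
  odds <- (p0 / (1 - p0)) * or_per_point^points
  odds / (1 + odds)
}

#' Fit the default Gupta score-to-probability mapper
#'
#' The published Gupta simple score has no printed per-score probabilities;
#' its companion "primary" model maps score to risk through a cubic spline.
#' This fits that mapping on a reference cohort: a logistic regression of
#' the outcome on a restricted cubic spline of the score, with 4 knots at
#' the score quantiles 0.05, 0.35, 0.65 and 0.95. When ties leave fewer
#' than 3 distinct knots the fit degrades gracefully to a plain logistic
#' regression on the score. The fit is deterministic; the returned object
#' records knots and coefficients so a run can be audited or the mapper
#' replaced by externally published coefficients.
#'
#' @param scores Gupta score points of the reference cohort.
#' @param outcomes Binary outcome (0/1 or logical) of the reference cohort.
#' @param knot_quantiles Score quantiles at which to place knots.
#' @return An object of class `caki_mapper` with `predict()` support.
#' @export
fit_gupta_mapper <- function(scores, outcomes,
                             knot_quantiles = c(0.05, 0.35, 0.65, 0.95)) {
  outcomes <- .as_binary(outcomes)
  if (length(scores) != length(outcomes))
    stop("scores and outcomes differ in length", call. = FALSE)
  knots <- unique(as.numeric(stats::quantile(scores, knot_quantiles,
                                             type = 7, names = FALSE)))
  fit <- NULL
  if (length(knots) >= 3) {
    basis <- rcs_basis(scores, knots)
    fit <- stats::glm.fit(cbind(1, basis), outcomes,
                          family = stats::binomial())
    # the mapper contract requires a monotone score -> probability curve;
    # a spline fit with a weak signal can wiggle, in which case the fit
    # degrades to the strictly monotone linear-logistic form
    grid <- seq(min(scores), max(scores), length.out = 200)
    eta <- drop(cbind(1, rcs_basis(grid, knots)) %*% fit$coefficients)
    if (anyNA(eta) || any(diff(eta) <= 0)) fit <- NULL
  }
  if (is.null(fit)) {
    knots <- numeric(0)
    fit <- stats::glm.fit(cbind(1, scores), outcomes,
                          family = stats::binomial())
  }
  structure(list(type = "rcs_logistic", knots = knots,
                 coefficients = unname(fit$coefficients),
                 n = length(scores), events = sum(outcomes),
                 converged = fit$converged,
                 mapper_id = sprintf("rcs%d-logistic", max(length(knots), 2L))),
            class = "caki_mapper")
}

#' Restricted cubic spline basis (Harrell parameterisation)
#'
#' Truncated-power restricted cubic spline basis, linear beyond the outer
#' knots, scaled by the squared outer-knot span. For k knots it returns
#' k - 1 columns (the linear term plus k - 2 nonlinear terms).
#'
#' @param x Numeric vector.
#' @param knots Increasing knot locations (length >= 3).
#' @return Matrix with `length(knots) - 1` columns.
#' @keywords internal
rcs_basis <- function(x, knots) {
  k <- length(knots)
  stopifnot(k >= 3)
  knots <- sort(knots)
  tk <- knots[k]; tk1 <- knots[k - 1]; span2 <- (tk - knots[1])^2
  cube <- function(u) pmax(u, 0)^3
  out <- matrix(0, length(x), k - 1)
  out[, 1] <- x
  for (j in seq_len(k - 2)) {
    tj <- knots[j]
    out[, j + 1] <- (cube(x - tj) -
      cube(x - tk1) * (tk - tj) / (tk - tk1) +
      cube(x - tk)  * (tk1 - tj) / (tk - tk1)) / span2
  }
  colnames(out) <- c("x", if (k > 2) paste0("x", seq_len(k - 2)))
  out
}

#' Evaluate a Gupta probability mapper
#'
#' @param points Score points at which to evaluate.
#' @param mapper A `caki_mapper` from [fit_gupta_mapper()], or any function
#'   mapping points to probabilities (the pluggable slot for published
#'   primary-model coefficients).
#' @return Predicted probabilities.
#' @export
gupta_probability <- function(points, mapper) {
  if (is.function(mapper)) {
    p <- mapper(points)
  } else if (inherits(mapper, "caki_mapper")) {
    p <- predict(mapper, points)
  } else {
    stop("mapper must be a caki_mapper or a function; fit one with ",
         "fit_gupta_mapper()", call. = FALSE)
  }
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("mapper returned values outside [0, 1]", call. = FALSE)
  p
}

#' @export
predict.caki_mapper <- function(object, newdata, ...) {
  x <- newdata
  if (length(object$knots) >= 3) {
    eta <- drop(cbind(1, rcs_basis(x, object$knots)) %*% object$coefficients)
  } else {
    eta <- object$coefficients[1] + object$coefficients[2] * x
  }
  stats::plogis(eta)
}

#' @export
print.caki_mapper <- function(x, ...) {
  cat("Gupta score-to-probability mapper (", x$mapper_id, ")\n", sep = "")
  cat("  knots:", if (length(x$knots)) paste(round(x$knots, 3), collapse = ", ")
                  else "none (linear fallback)", "\n")
  cat("  fit on n =", x$n, "with", x$events, "events\n")
  invisible(x)
}

#' Serialise a mapper to JSON
#'
#' @param mapper A `caki_mapper`.
#' @param path Optional file path; if `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to file.
#' @export
mapper_to_json <- function(mapper, path = NULL) {
  stopifnot(inherits(mapper, "caki_mapper"))
  js <- jsonlite::toJSON(unclass(mapper), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}

#' Read a mapper back from JSON
#' @param path File written by [mapper_to_json()].
#' @return A `caki_mapper`.
#' @export
mapper_from_json <- function(path) {
  x <- jsonlite::fromJSON(path)
  x$knots <- as.numeric(x$knots)
  structure(x, class = "caki_mapper")
}

.as_binary <- function(y) {
  if (is.logical(y)) y <- as.integer(y)
  if (is.factor(y)) y <- as.integer(y) - 1L
  if (!all(y %in% c(0, 1)))
    stop("outcomes must be binary (0/1 or logical)", call. = FALSE)
  as.integer(y)
}
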