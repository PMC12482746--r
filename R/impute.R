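#' Fit a regression-based single imputer for baseline labs
#'
#' For every laboratory variable with missing values, fits an ordinary
#' least-squares regression of that lab on the always-complete covariates
#' (age, sex, cisplatin dose, baseline creatinine, hypertension, diabetes,
#' smoking) using complete cases. Imputation then fills missing cells with
#' the conditional mean — deterministic single imputation with no residual
#' draw. Outcome labels are never used as predictors, so the imputer cannot
#' leak outcome information into the scores.
#'
#' @param cohort Cohort data frame with covariate columns and the lab
#'   columns in `labs`.
#' @param labs Lab columns eligible for imputation. Default: albumin,
#'   hemoglobin, wbc, platelets, magnesium.
#' @return Object of class `caki_imputer`: one linear sub-model per
#'   incomplete lab (coefficients, n used, residual sd).
#' @export
fit_imputer <- function(cohort,
                        labs = c("albumin", "hemoglobin", "wbc",
                                 "platelets", "magnesium")) {
  predictors <- c("age", "sex_male", "cddp_dose", "baseline_creatinine",
                  "hypertension", "diabetes", "smoker")
  X <- .imputer_design(cohort, predictors)
  labs <- intersect(labs, names(cohort))
  models <- list()
  for (lab in labs) {
    v <- cohort[[lab]]
    if (!anyNA(v)) next
    cc <- !is.na(v) & stats::complete.cases(X)
    if (sum(cc) < ncol(X) + 2)
      stop("cannot fit imputation model for '", lab, "': only ", sum(cc),
           " complete cases for ", ncol(X), " predictors", call. = FALSE)
    if (sum(cc) < 20)
      warning("imputation model for '", lab, "' fit on fewer than 20 ",
              "complete cases", call. = FALSE)
    fit <- stats::lm.fit(cbind(`(Intercept)` = 1, as.matrix(X[cc, ])), v[cc])
    resid_sd <- sqrt(sum(fit$residuals^2) /
                       max(fit$df.residual, 1))
    models[[lab]] <- list(coefficients = fit$coefficients,
                          predictors = predictors,
                          n = sum(cc), residual_sd = resid_sd)
  }
  structure(list(models = models, predictors = predictors),
            class = "caki_imputer")
}

.imputer_design <- function(cohort, predictors) {
  need <- setdiff(predictors, "sex_male")
  miss <- setdiff(c(need, "sex"), names(cohort))
  if (length(miss))
    stop("cohort lacks imputer predictor column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  data.frame(age = cohort$age,
             sex_male = as.numeric(cohort$sex == "male"),
             cddp_dose = cohort$cddp_dose,
             baseline_creatinine = cohort$baseline_creatinine,
             hypertension = as.numeric(cohort$hypertension),
             diabetes = as.numeric(cohort$diabetes),
             smoker = as.numeric(cohort$smoker))
}

#' Impute missing baseline labs
#'
#' Replaces missing lab cells with the conditional mean from the fitted
#' imputer; observed cells are never modified, imputed values are clipped
#' to positive physiological support, and a per-cell provenance flag
#' `imputed_<lab>` is appended. Idempotent: imputing an already-complete
#' cohort is the identity.
#'
#' @param cohort Cohort data frame.
#' @param model A `caki_imputer` from [fit_imputer()]. Default fits one on
#'   `cohort` itself.
#' @return The cohort with labs filled and flag columns appended.
#' @export
impute <- function(cohort, model = fit_imputer(cohort)) {
  stopifnot(inherits(model, "caki_imputer"))
  X <- as.matrix(cbind(1, .imputer_design(cohort, model$predictors)))
  for (lab in names(model$models)) {
    if (!lab %in% names(cohort)) next
    m <- model$models[[lab]]
    is_miss <- is.na(cohort[[lab]])
    flag_col <- paste0("imputed_", lab)
    cohort[[flag_col]] <- is_miss
    if (!any(is_miss)) next
    if (anyNA(X[is_miss, , drop = FALSE]))
      stop("record missing an imputer predictor for '", lab,
           "': cohort schema violated", call. = FALSE)
    pred <- drop(X[is_miss, , drop = FALSE] %*% m$coefficients)
    cohort[[lab]][is_miss] <- pmax(pred, 1e-6)
  }
  incomplete <- names(cohort)[vapply(cohort, anyNA, logical(1))]
  incomplete <- intersect(incomplete,
                          c("albumin", "hemoglobin", "wbc", "platelets",
                            "magnesium"))
  if (length(incomplete))
    stop("imputer does not cover incomplete lab(s): ",
         paste(incomplete, collapse = ", "), call. = FALSE)
  cohort
}

#' @export
print.caki_imputer <- function(x, ...) {
  cat("Regression-based single imputer:", length(x$models),
      "lab sub-model(s)\n")
  for (lab in names(x$models)) {
    m <- x$models[[lab]]
    cat(sprintf("  %-11s n = %5d  residual sd = %.4f\n",
                lab, m$n, m$residual_sd))
  }
  invisible(x)
}

#' Export imputation coefficients to JSON
#' @param model A `caki_imputer`.
#' @param path Optional file path.
#' @return JSON string (invisibly when written).
#' @export
imputer_to_json <- function(model, path = NULL) {
  stopifnot(inherits(model, "caki_imputer"))
  js <- jsonlite::toJSON(lapply(model$models, function(m)
    list(coefficients = as.list(m$coefficients), n = m$n,
         residual_sd = m$residual_sd)), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
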