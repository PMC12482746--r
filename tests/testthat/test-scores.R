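test_that("Motwani point assignments match the published table", {
  # age 61-70 (1.5) + hypertension (2) + dose 101-150 (1) + albumin <= 3.5 (2)
  expect_equal(motwani_score(65, TRUE, 120, 3.4), 6.5)
  # all-zero bins, including the inclusive edges 60 / 100 / > 3.5
  expect_equal(motwani_score(50, FALSE, 100, 4.0), 0)
  expect_equal(motwani_score(60, FALSE, 100, 3.51), 0)
  # per-item boundaries
  expect_equal(motwani_score(61, FALSE, 100, 4), 1.5)
  expect_equal(motwani_score(71, FALSE, 100, 4), 2.5)
  expect_equal(motwani_score(50, FALSE, 101, 4), 1)
  expect_equal(motwani_score(50, FALSE, 151, 4), 3)
  expect_equal(motwani_score(50, FALSE, 100, 3.5), 2)
})

test_that("Motwani score maximum over all bins is 9.5 (enumeration)", {
  # 2.5 (age > 70) + 2 (hypertension) + 3 (dose > 150) + 2 (albumin <= 3.5)
  ages <- c(50, 65, 75); doses <- c(80, 120, 180)
  albs <- c(3.0, 4.0); htn <- c(TRUE, FALSE)
  grid <- expand.grid(age = ages, htn = htn, dose = doses, alb = albs)
  all_scores <- motwani_score(grid$age, grid$htn, grid$dose, grid$alb)
  expect_equal(max(all_scores), 9.5)
  expect_equal(min(all_scores), 0)
  expect_true(all(all_scores * 2 == round(all_scores * 2)))
})

test_that("Gupta point assignments match the published table", {
  # 4.5 + 1 + 1 + 1 + 7.5 + 1.5 + 1.5 + 1.5 + 1 = 20.5
  expect_equal(gupta_score(72, TRUE, TRUE, TRUE, 180, 10.5, 13, 3.0, 1.8),
               20.5)
  expect_equal(gupta_score(40, FALSE, FALSE, FALSE, 50, 13, 8, 4.0, 2.2), 0)
  # magnesium-excluded variant drops exactly the magnesium point
  expect_equal(gupta_score(72, TRUE, TRUE, TRUE, 180, 10.5, 13, 3.0,
                           include_magnesium = FALSE), 19.5)
  # albumin band boundaries: > 3.8 is 0; [3.3, 3.8] is 1; < 3.3 is 1.5
  expect_equal(gupta_score(40, FALSE, FALSE, FALSE, 50, 13, 8, 3.8, 2.2), 1)
  expect_equal(gupta_score(40, FALSE, FALSE, FALSE, 50, 13, 8, 3.3, 2.2), 1)
  expect_equal(gupta_score(40, FALSE, FALSE, FALSE, 50, 13, 8, 3.29, 2.2),
               1.5)
  # hemoglobin 11.95 sits inside the printed 11.0-11.9 / >= 12.0 gap and
  # joins the band below 12
  expect_equal(gupta_score(40, FALSE, FALSE, FALSE, 50, 11.95, 8, 4, 2.2), 1)
})

test_that("Gupta score maximum over all bins is 22.5 (enumeration)", {
  grid <- expand.grid(age = c(40, 50, 65, 75), dose = c(40, 60, 90, 110,
                                                        140, 180, 250),
                      hb = c(10, 11.5, 13), wbc = c(8, 14),
                      alb = c(3.0, 3.5, 4.2), mg = c(1.8, 2.2))
  s <- gupta_score(grid$age, TRUE, TRUE, TRUE, grid$dose, grid$hb,
                   grid$wbc, grid$alb, grid$mg)
  expect_equal(max(s), 22.5)
  s0 <- gupta_score(grid$age, FALSE, FALSE, FALSE, grid$dose, grid$hb,
                    grid$wbc, grid$alb, grid$mg)
  expect_equal(min(s0), 0)
})

test_that("every admissible covariate vector maps to exactly one half-point total", {
  x <- random_score_inputs(2000, seed = 42)
  m <- motwani_score(x$age, x$hypertension, x$cddp_dose, x$albumin)
  g <- gupta_score(x$age, x$hypertension, x$diabetes, x$smoker,
                   x$cddp_dose, x$hemoglobin, x$wbc, x$albumin, x$magnesium)
  expect_false(anyNA(m)); expect_false(anyNA(g))
  expect_true(all(m >= 0 & m <= 10))
  expect_true(all(g >= 0 & g <= 22.5))
  expect_true(all(abs(m * 2 - round(m * 2)) < 1e-9))
  expect_true(all(abs(g * 2 - round(g * 2)) < 1e-9))
})

test_that("worsening any single predictor never decreases either score", {
  x <- random_score_inputs(500, seed = 7)
  g0 <- gupta_score(x$age, x$hypertension, x$diabetes, x$smoker,
                    x$cddp_dose, x$hemoglobin, x$wbc, x$albumin,
                    x$magnesium)
  worse <- list(
    gupta_score(x$age + 5, x$hypertension, x$diabetes, x$smoker,
                x$cddp_dose, x$hemoglobin, x$wbc, x$albumin, x$magnesium),
    gupta_score(x$age, TRUE, x$diabetes, x$smoker, x$cddp_dose,
                x$hemoglobin, x$wbc, x$albumin, x$magnesium),
    gupta_score(x$age, x$hypertension, TRUE, TRUE, x$cddp_dose,
                x$hemoglobin, x$wbc, x$albumin, x$magnesium),
    gupta_score(x$age, x$hypertension, x$diabetes, x$smoker,
                x$cddp_dose * 1.3, x$hemoglobin, x$wbc, x$albumin,
                x$magnesium),
    gupta_score(x$age, x$hypertension, x$diabetes, x$smoker, x$cddp_dose,
                x$hemoglobin - 1.2, x$wbc, x$albumin, x$magnesium),
    gupta_score(x$age, x$hypertension, x$diabetes, x$smoker, x$cddp_dose,
                x$hemoglobin, x$wbc + 5, x$albumin, x$magnesium),
    gupta_score(x$age, x$hypertension, x$diabetes, x$smoker, x$cddp_dose,
                x$hemoglobin, x$wbc, x$albumin - 0.6, x$magnesium),
    gupta_score(x$age, x$hypertension, x$diabetes, x$smoker, x$cddp_dose,
                x$hemoglobin, x$wbc, x$albumin, x$magnesium - 0.4))
  for (w in worse) expect_true(all(w >= g0))
  m0 <- motwani_score(x$age, x$hypertension, x$cddp_dose, x$albumin)
  expect_true(all(motwani_score(x$age + 5, x$hypertension, x$cddp_dose,
                                x$albumin) >= m0))
  expect_true(all(motwani_score(x$age, x$hypertension, x$cddp_dose,
                                x$albumin - 0.6) >= m0))
  # excluding magnesium removes 0 or 1 point exactly
  gx <- gupta_score(x$age, x$hypertension, x$diabetes, x$smoker,
                    x$cddp_dose, x$hemoglobin, x$wbc, x$albumin,
                    include_magnesium = FALSE)
  expect_true(all((g0 - gx) %in% c(0, 1)))
})

test_that("missing predictors are reported by name", {
  expect_error(motwani_score(65, TRUE, 120, NA), "albumin")
  expect_error(gupta_score(65, TRUE, FALSE, FALSE, 120, 12, 6, 3.9, NULL),
               "magnesium")
})

test_that("risk groups follow the published cutoffs", {
  expect_equal(as.character(gupta_risk_group(c(0, 5.5, 6, 9.5, 10, 15.5, 16, 22.5))),
               c("low", "low", "moderate", "moderate", "high", "high",
                 "very_high", "very_high"))
  expect_error(gupta_risk_group(-1), "non-negative")
  expect_error(gupta_risk_group(7.25), "half-point")
  # exhaustive and disjoint over the whole half-point grid
  grid <- seq(0, 22.5, by = 0.5)
  expect_false(anyNA(gupta_risk_group(grid)))
})

test_that("Motwani probability mapping uses baseline 0.04 and OR 1.49", {
  expect_equal(motwani_probability(0), 0.04)
  expect_equal(motwani_probability(6.5), 0.3576, tolerance = 1e-3)
  # consecutive-score odds ratio is exactly 1.49 across the whole range
  s <- 0:9
  odds <- function(p) p / (1 - p)
  ratios <- odds(motwani_probability(s + 1)) / odds(motwani_probability(s))
  expect_equal(ratios, rep(1.49, 10), tolerance = 1e-12)
  # strictly increasing
  p <- motwani_probability(seq(0, 10, by = 0.5))
  expect_true(all(diff(p) > 0))
  expect_error(motwani_probability(-1), "non-negative")
})

test_that("Gupta probability mapper is pluggable, monotone and deterministic", {
  # plug-in contract: any function works
  expect_equal(gupta_probability(c(0, 5, 20), function(s) rep(0.05, length(s))),
               rep(0.05, 3))
  set.seed(3)
  s <- sample(seq(0, 20, by = 0.5), 800, replace = TRUE,
              prob = dnorm(seq(0, 20, by = 0.5), 9, 3))
  y <- as.integer(runif(800) < plogis(-4 + 0.25 * s))
  m1 <- fit_gupta_mapper(s, y)
  m2 <- fit_gupta_mapper(s, y)
  expect_equal(predict(m1, seq(0, 20, 0.5)), predict(m2, seq(0, 20, 0.5)))
  p <- gupta_probability(seq(min(s), max(s), by = 0.5), m1)
  expect_true(all(p > 0 & p < 1))
  # non-decreasing over the observed score range for a monotone signal
  expect_true(all(diff(p) > -1e-6))
  # JSON round trip preserves predictions
  f <- withr::local_tempfile(fileext = ".json")
  mapper_to_json(m1, f)
  m3 <- mapper_from_json(f)
  expect_equal(predict(m3, seq(0, 20, 0.5)), predict(m1, seq(0, 20, 0.5)))
  expect_error(gupta_probability(5, "not a mapper"), "mapper")
})

test_that("restricted cubic spline basis is linear beyond the outer knots", {
  kn <- c(2, 5, 9, 14)
  x <- seq(-5, 30, by = 0.25)
  b <- rcs_basis(x, kn)
  expect_equal(ncol(b), 3)
  # second differences vanish outside the knot span (linearity)
  for (j in 1:3) {
    tail_region <- x > 14.5
    d2 <- diff(diff(b[tail_region, j]))
    expect_true(all(abs(d2) < 1e-8))
  }
  expect_equal(b[, 1], x)
})
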