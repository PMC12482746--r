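test_that("the default configuration is frozen at the study conditions", {
  cfg <- default_config()
  expect_equal(cfg$n_patients, 1684L)
  expect_equal(unname(cfg$missingness_rates["magnesium"]), 0.612)
  expect_equal(unname(cfg$missingness_rates["albumin"]), 0.060)
  expect_equal(cfg$outcome_params$target_caki, 0.110)
  expect_equal(cfg$outcome_params$target_severe, 0.021)
  # idempotent: two calls give identical configurations
  expect_identical(default_config(), default_config())
  expect_silent(validate_config(cfg))
})

test_that("invalid configurations are rejected naming the offending field", {
  cfg <- default_config()
  cfg$n_patients <- 0L
  expect_error(validate_config(cfg), "n_patients")
  cfg <- default_config()
  cfg$missingness_rates["magnesium"] <- 1.2
  expect_error(validate_config(cfg), "missingness_rates")
  cfg <- default_config()
  cfg$outcome_params$target_severe <- 0.5
  expect_error(validate_config(cfg), "target_severe")
  cfg <- default_config()
  cfg$rrt_rate_given_severe <- -0.1
  expect_error(validate_config(cfg), "rrt_rate_given_severe")
  cfg <- default_config()
  cfg$covariate_params$albumin$sdlog <- 0
  expect_error(validate_config(cfg), "albumin")
})

test_that("generation is deterministic: identical (config, seed) gives byte-identical CSV", {
  cfg <- default_config(n_patients = 300)
  s1 <- generate_cohort(cfg, seed = 42)
  s2 <- generate_cohort(cfg, seed = 42)
  f1 <- withr::local_tempfile(fileext = ".csv")
  f2 <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(apply_missingness(s1$cohort, cfg, seed = 43), f1)
  write_cohort_csv(apply_missingness(s2$cohort, cfg, seed = 43), f2)
  expect_identical(readLines(f1), readLines(f2))
  # a different seed changes the cohort
  s3 <- generate_cohort(cfg, seed = 43)
  expect_false(identical(s1$cohort$age, s3$cohort$age))
})

test_that("labelling the synthesized trajectories reproduces the sampled truth exactly", {
  for (seed in c(1, 17, 3021)) {
    sim <- generate_cohort(default_config(n_patients = 1000), seed = seed)
    lab <- label_cohort(sim$cohort)
    expect_identical(lab$stage, sim$truth$class_true)
    expect_identical(lab$caki, sim$truth$class_true != "none")
    expect_identical(lab$severe_caki, sim$truth$class_true == "stage2plus")
  }
})

test_that("RRT appears only in the severe class", {
  sim <- generate_cohort(default_config(n_patients = 5000), seed = 2)
  expect_true(all(sim$cohort$patient_id[sim$cohort$rrt_within_window] %in%
                    sim$truth$patient_id[sim$truth$class_true == "stage2plus"]))
})

test_that("covariate marginals are recovered at large n", {
  sim <- generate_cohort(default_config(n_patients = 50000), seed = 99)
  coh <- sim$cohort
  targets <- list(age = c(58, 66, 71),
                  cddp_dose = c(90, 110, 130),
                  baseline_creatinine = c(0.63, 0.75, 0.87),
                  albumin = c(3.5, 3.9, 4.2),
                  hemoglobin = c(11.3, 12.5, 13.6),
                  wbc = c(4.64, 5.99, 7.56),
                  platelets = c(203, 256, 313),
                  magnesium = c(2.00, 2.05, 2.10))
  for (v in names(targets)) {
    q <- quantile(coh[[v]], c(0.25, 0.5, 0.75), names = FALSE)
    expect_true(all(abs(q / targets[[v]] - 1) < 0.03),
                label = sprintf("%s quantiles within 3%% (got %s)",
                                v, paste(round(q, 2), collapse = "/")))
  }
  expect_equal(mean(coh$sex == "male"), 0.667, tolerance = 0.01)
  expect_equal(mean(coh$hypertension), 0.353, tolerance = 0.01)
  expect_equal(mean(coh$diabetes), 0.121, tolerance = 0.01)
  expect_equal(mean(coh$smoker), 0.648, tolerance = 0.01)
  expect_true(all(coh$age >= 18 & coh$age <= 95))
  expect_true(all(coh$cddp_dose > 0))
  # positive age-hypertension association is present
  expect_gt(mean(coh$age[coh$hypertension]), mean(coh$age[!coh$hypertension]))
})

test_that("outcome prevalences are recovered at large n", {
  sim <- generate_cohort(default_config(n_patients = 50000), seed = 7)
  lab <- label_cohort(sim$cohort)
  se_caki <- sqrt(0.110 * 0.890 / 50000)
  se_sev <- sqrt(0.021 * 0.979 / 50000)
  expect_lt(abs(mean(lab$caki) - 0.110), 3 * se_caki)
  expect_lt(abs(mean(lab$severe_caki) - 0.021), 3 * se_sev)
})

test_that("degenerate prevalence targets force the trajectory classes", {
  cfg <- default_config(n_patients = 400)
  cfg$outcome_params$target_caki <- 0
  cfg$outcome_params$target_severe <- 0
  sim <- generate_cohort(cfg, seed = 3)
  lab <- label_cohort(sim$cohort)
  expect_false(any(lab$caki))
  expect_false(any(sim$cohort$rrt_within_window))

  cfg$outcome_params$target_caki <- 1
  cfg$outcome_params$target_severe <- 1
  cfg$rrt_rate_given_severe <- 0
  sim <- generate_cohort(cfg, seed = 3)
  lab <- label_cohort(sim$cohort)
  expect_true(all(lab$severe_caki))
  expect_true(all(lab$fold_change >= 2.0))
  expect_false(any(sim$cohort$rrt_within_window))
})

test_that("missingness masking hits its configured rates", {
  cfg <- default_config(n_patients = 10000)
  sim <- generate_cohort(cfg, seed = 5)
  # rate 0 leaves records unchanged
  cfg0 <- cfg; cfg0$missingness_rates[] <- 0
  expect_identical(apply_missingness(sim$cohort, cfg0, seed = 6),
                   sim$cohort)
  # rate 1 masks everything
  cfg1 <- cfg; cfg1$missingness_rates["magnesium"] <- 1
  expect_true(all(is.na(apply_missingness(sim$cohort, cfg1,
                                          seed = 6)$magnesium)))
  # the default magnesium rate lands in its binomial 99% interval
  masked <- apply_missingness(sim$cohort, cfg, seed = 6)
  expect_gt(mean(is.na(masked$magnesium)), 0.60)
  expect_lt(mean(is.na(masked$magnesium)), 0.625)
  expect_lt(abs(mean(is.na(masked$albumin)) - 0.06), 0.01)
  # out-of-range rate errors
  cfgbad <- cfg; cfgbad$missingness_rates["albumin"] <- -0.1
  expect_error(apply_missingness(sim$cohort, cfgbad, seed = 6), "\\[0, 1\\]")
  # MAR mode: masking probability rises with age, marginal roughly kept
  mar <- apply_missingness(sim$cohort, cfg, seed = 6, mechanism = "mar")
  miss_by_age <- tapply(is.na(mar$magnesium), sim$cohort$age > 66, mean)
  expect_gt(miss_by_age[["TRUE"]], miss_by_age[["FALSE"]])
  expect_equal(mean(is.na(mar$magnesium)), 0.612, tolerance = 0.05)
})

test_that("cohort CSV round-trips through write and read", {
  sim <- generate_cohort(default_config(n_patients = 150), seed = 11)
  coh <- apply_missingness(sim$cohort, default_config(), seed = 12)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh, f)
  back <- read_cohort_csv(f)
  expect_equal(back$age, coh$age, tolerance = 1e-12)
  expect_identical(back$hypertension, coh$hypertension)
  expect_identical(is.na(back$magnesium), is.na(coh$magnesium))
  expect_identical(back$trajectory, coh$trajectory)
  lab1 <- label_cohort(coh); lab2 <- label_cohort(back)
  expect_identical(lab1$stage, lab2$stage)
})

test_that("eGFR by the Japanese equation behaves sensibly", {
  # higher creatinine and age lower eGFR; female coefficient 0.739
  expect_gt(egfr_jsn(0.6, 50, "male"), egfr_jsn(1.2, 50, "male"))
  expect_gt(egfr_jsn(0.8, 40, "male"), egfr_jsn(0.8, 80, "male"))
  expect_equal(egfr_jsn(0.8, 60, "female") / egfr_jsn(0.8, 60, "male"),
               0.739, tolerance = 1e-12)
  # cohort median lands near the reference description
  sim <- generate_cohort(default_config(n_patients = 20000), seed = 21)
  med <- median(egfr_jsn(sim$cohort$baseline_creatinine, sim$cohort$age,
                         sim$cohort$sex))
  expect_gt(med, 64); expect_lt(med, 84)
  desc <- describe_cohort(sim$cohort)
  expect_true("Age, years" %in% desc$characteristic)
})
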