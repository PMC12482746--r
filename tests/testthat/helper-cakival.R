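# Shared fixture builders; everything is generated in code.

# Brute-force O(n^2) pairwise-concordance oracle for the AUROC.
auroc_oracle <- function(pred, y) {
  y <- as.integer(y)
  ev <- pred[y == 1]; ne <- pred[y == 0]
  total <- 0
  for (e in ev) total <- total + sum(e > ne) + 0.5 * sum(e == ne)
  total / (length(ev) * length(ne))
}

# Minimal complete patient record as a one-row data frame.
make_record <- function(age = 65, sex = "male", hypertension = TRUE,
                        diabetes = FALSE, smoker = FALSE, cddp_dose = 120,
                        baseline_creatinine = 0.75, albumin = 3.4,
                        hemoglobin = 12.5, wbc = 6, platelets = 250,
                        magnesium = 2.05, rrt_within_window = FALSE,
                        trajectory = "3:0.8;7:0.82;14:0.78",
                        patient_id = "P00001") {
  data.frame(patient_id = patient_id, age = age, sex = sex,
             hypertension = hypertension, diabetes = diabetes,
             smoker = smoker, cddp_dose = cddp_dose,
             baseline_creatinine = baseline_creatinine, albumin = albumin,
             hemoglobin = hemoglobin, wbc = wbc, platelets = platelets,
             magnesium = magnesium, rrt_within_window = rrt_within_window,
             trajectory = trajectory, stringsAsFactors = FALSE)
}

# Random admissible covariate vectors for property tests over the score
# bins (values concentrated around the printed bin edges on purpose).
random_score_inputs <- function(n, seed) {
  set.seed(seed)
  edge_jitter <- function(edges, lo, hi) {
    base <- sample(c(edges, runif(4, lo, hi)), n, replace = TRUE)
    pmin(pmax(base + sample(c(-0.01, 0, 0.01), n, replace = TRUE), lo), hi)
  }
  data.frame(
    age = edge_jitter(c(45, 46, 60, 61, 70, 71), 18, 95),
    hypertension = runif(n) < 0.5,
    diabetes = runif(n) < 0.5,
    smoker = runif(n) < 0.5,
    cddp_dose = edge_jitter(c(50, 51, 75, 76, 100, 101, 125, 126, 150,
                              151, 200, 201), 10, 300),
    hemoglobin = edge_jitter(c(10.9, 11, 11.9, 12), 6, 18),
    wbc = edge_jitter(c(11.9, 12, 12.1), 2, 30),
    albumin = edge_jitter(c(3.2, 3.3, 3.5, 3.8, 3.9), 1.5, 5.5),
    magnesium = edge_jitter(c(1.9, 2, 2.1), 1, 3))
}

# Calibrated probabilities + outcomes drawn from them.
calibrated_sample <- function(n, seed, intercept = -2.2, slope = 0.3) {
  set.seed(seed)
  s <- round(pmax(rnorm(n, 6, 3), 0) * 2) / 2
  p <- plogis(intercept + slope * s)
  list(scores = s, p = p, y = as.integer(runif(n) < p))
}
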