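# The reference worked example published with the 2008 general-CVD risk
# function: a 61-year-old female smoker, total cholesterol 180 mg/dL, HDL
# 47 mg/dL, untreated SBP 124 mmHg, no diabetes -> 10.48% 10-year risk.
reference_example <- data.frame(
  age = 61, sex = "female", total_chol = 180, hdl = 47, sbp = 124,
  bp_treated = FALSE, smoker = TRUE, diabetes = FALSE,
  stringsAsFactors = FALSE
)

random_records <- function(n, seed) {
  set.seed(seed)
  data.frame(
    age = runif(n, 30, 74),
    sex = sample(c("male", "female"), n, replace = TRUE),
    total_chol = runif(n, 120, 320),
    hdl = runif(n, 25, 90),
    sbp = runif(n, 95, 190),
    bp_treated = runif(n) < 0.3,
    smoker = runif(n) < 0.3,
    diabetes = runif(n) < 0.15,
    stringsAsFactors = FALSE
  )
}

test_that("the published worked example is reproduced to 0.1 percentage point", {
  risk <- framingham_risk(reference_example, lipid_unit = "mg/dL")
  expect_lt(abs(risk - 10.48), 0.1)
})

test_that("risk is monotone in each covariate with the expected sign", {
  base <- random_records(200, seed = 21)
  r0 <- framingham_risk(base, lipid_unit = "mg/dL")
  bump <- function(field, value) {
    rec <- base
    rec[[field]] <- if (is.logical(value)) value else rec[[field]] + value
    framingham_risk(rec, lipid_unit = "mg/dL")
  }
  expect_true(all(bump("age", 5) > r0))
  expect_true(all(bump("total_chol", 20) > r0))
  expect_true(all(bump("sbp", 10) > r0))
  expect_true(all(bump("hdl", 10) < r0))
  expect_true(all(bump("smoker", TRUE) >= r0))
  expect_true(all(bump("diabetes", TRUE) >= r0))
  expect_true(all(bump("smoker", TRUE)[!base$smoker] > r0[!base$smoker]))
  expect_true(all(bump("diabetes", TRUE)[!base$diabetes] > r0[!base$diabetes]))
})

test_that("identical records score identically and risks stay in (0, 100)", {
  rec <- random_records(500, seed = 8)
  r1 <- framingham_risk(rec, lipid_unit = "mg/dL")
  r2 <- framingham_risk(rec, lipid_unit = "mg/dL")
  expect_identical(r1, r2)
  expect_true(all(r1 > 0 & r1 < 100))
})

test_that("synthetic male cohorts score in range with mmol/L lipids", {
  coh <- gen_clinical(sim_config(n_subjects = 200, seed = 12))
  risk <- framingham_risk(coh$records)
  expect_true(all(risk > 0 & risk < 100))
  # unit handling: mmol/L input equals pre-converted mg/dL input
  rec <- coh$records
  rec$total_chol <- rec$total_chol * 38.67
  rec$hdl <- rec$hdl * 38.67
  expect_equal(framingham_risk(rec, lipid_unit = "mg/dL"), risk,
               tolerance = 1e-12)
})

test_that("a missing covariate raises an error naming it", {
  rec <- reference_example
  rec$hdl <- NA_real_
  expect_error(framingham_risk(rec, lipid_unit = "mg/dL"), "hdl")
  expect_error(framingham_risk(reference_example[, -3], lipid_unit = "mg/dL"),
               "total_chol")
})

test_that("incomplete coefficient files are rejected", {
  coefs <- jsonlite::read_json(system.file(
    "extdata", "framingham_general_cvd_2008.json", package = "metsynflux"
  ))
  coefs$male$ln_hdl <- NULL
  bad <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(coefs, bad, auto_unbox = TRUE)
  expect_error(framingham_coefficients(bad), "male")
})

test_that("dichotomization applies the >= 12% convention and partitions the cohort", {
  expect_equal(dichotomize_framingham(12), "high")
  expect_equal(dichotomize_framingham(11.9), "low")
  expect_equal(dichotomize_framingham(13), "high")
  risk <- framingham_risk(random_records(100, seed = 5), lipid_unit = "mg/dL")
  g <- dichotomize_framingham(risk)
  expect_equal(sum(g == "high") + sum(g == "low"), 100)
  expect_error(dichotomize_framingham(Inf), "finite")
})
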