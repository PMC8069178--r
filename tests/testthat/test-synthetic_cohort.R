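test_that("empty cohort is returned for n_subjects = 0, not an error", {
  coh <- gen_clinical(sim_config(n_subjects = 0))
  expect_equal(nrow(coh$records), 0)
  expect_length(coh$truth$ir_labels, 0)
  expect_length(coh$truth$true_suppression, 0)
})

test_that("invalid configuration fractions and indices are rejected", {
  expect_error(sim_config(ir_fraction = 1.2), "fraction")
  expect_error(sim_config(missing_rate = -0.1), "fraction")
  expect_error(sim_config(n_metabolites = 10, ir_effect_metabolites = 1:14,
                          fram_effect_metabolites = integer(0)),
               "indices")
  expect_error(sim_config(ir_effect_metabolites = 1:5,
                          fram_effect_metabolites = 5:10), "disjoint")
  expect_error(sim_config(clamp_true_suppression = 120), "\\[0, 100\\]")
})

test_that("identical configs give bit-identical cohorts, tables and clamps", {
  cfg <- sim_config(n_subjects = 40, n_metabolites = 60)
  a <- gen_clinical(cfg)
  b <- gen_clinical(cfg)
  expect_identical(a, b)
  ta <- gen_metabolites(a$records, a$truth, cfg)
  tb <- gen_metabolites(b$records, b$truth, cfg)
  expect_identical(ta$abundances, tb$abundances)
  ca <- gen_clamp(a$records[1:5, ], local({t <- a$truth; t$true_suppression <- t$true_suppression[1:5]; t}), cfg)
  cb <- gen_clamp(b$records[1:5, ], local({t <- b$truth; t$true_suppression <- t$true_suppression[1:5]; t}), cfg)
  expect_identical(ca, cb)
})

test_that("clinical marginals are calibrated to the cohort targets", {
  coh <- gen_clinical(sim_config(n_subjects = 10000, seed = 3))
  r <- coh$records
  expect_lt(abs(median(r$bmi) - 33.91), 1)
  expect_lt(abs(median(r$fasting_glucose) - 5.72), 0.2)
  expect_true(all(r$sbp > r$dbp))
  expect_true(all(r$age > 0))
  expect_true(all(r$sex == "male"))
  expect_true(all(r[c("total_chol", "hdl", "ldl", "triglycerides",
                      "fasting_glucose", "fasting_insulin")] > 0))
  # insulin separates by planted IR status, as in the cohort it emulates
  expect_gt(median(r$fasting_insulin[coh$truth$is_ir]),
            median(r$fasting_insulin[!coh$truth$is_ir]))
  # measured Rd is consistent with the IR labels by construction
  expect_identical(classify_ir(r$rd), coh$truth$ir_labels)
})

test_that("default metabolite panel has 917 annotated columns", {
  coh <- gen_clinical(sim_config(n_subjects = 20))
  tab <- gen_metabolites(coh$records, coh$truth, sim_config(n_subjects = 20))
  expect_equal(ncol(tab$abundances), 917)
  expect_equal(nrow(tab$annotations), 917)
  expect_false(any(is.na(tab$annotations$superpathway)))
  expect_gt(sum(tab$annotations$superpathway == "Lipid"), 300)
})

test_that("planted IR effect realizes the configured standardized log shift", {
  diffs <- unlist(lapply(1:100, function(r) {
    cfg <- sim_config(seed = 2000 + r, n_subjects = 132, n_metabolites = 50,
                      ir_effect_metabolites = 1:14, ir_effect_size = 1,
                      fram_effect_metabolites = integer(0),
                      missing_rate = 0)
    coh <- gen_clinical(cfg)
    tab <- gen_metabolites(coh$records, coh$truth, cfg)
    lx <- log(tab$abundances[, 1:14, drop = FALSE])
    vapply(1:14, function(j) {
      (mean(lx[coh$truth$is_ir, j]) - mean(lx[!coh$truth$is_ir, j])) /
        pooled_sd(lx[, j], coh$truth$is_ir)
    }, numeric(1))
  }))
  expect_lt(abs(mean(diffs) - 1), 0.1)
})

test_that("null generator is calibrated: ~5% of metabolites reach p < 0.05", {
  fracs <- vapply(1:200, function(r) {
    cfg <- sim_config(seed = 4000 + r, n_subjects = 60, n_metabolites = 100,
                      ir_effect_metabolites = integer(0),
                      fram_effect_metabolites = integer(0),
                      missing_rate = 0)
    coh <- gen_clinical(cfg)
    tab <- gen_metabolites(coh$records, coh$truth, cfg)
    p <- apply(tab$abundances, 2, function(col) {
      mann_whitney_u(col[coh$truth$is_ir], col[!coh$truth$is_ir])$p_value
    })
    mean(p < 0.05)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - 0.05), 0.01)
})

test_that("missingness is strictly left-censored below the detection limit", {
  cfg <- sim_config(seed = 9, n_subjects = 80, n_metabolites = 120)
  cfg0 <- sim_config(seed = 9, n_subjects = 80, n_metabolites = 120,
                     missing_rate = 0)
  coh <- gen_clinical(cfg)
  tab <- gen_metabolites(coh$records, coh$truth, cfg)
  latent <- gen_metabolites(coh$records, coh$truth, cfg0)$abundances
  limits <- attr(tab, "detection_limits")
  miss <- which(is.na(tab$abundances), arr.ind = TRUE)
  expect_gt(nrow(miss), 0)
  expect_true(all(latent[miss] < limits[miss[, "col"]]))
})

test_that("clamp forward model reaches the dilution steady state F/(Ra+F)", {
  cfg <- sim_config(clamp_true_suppression = 0, clamp_noise_cv = 0,
                    clamp = list(times = c(-30, 0, 600, 900, 1000)))
  coh <- gen_clinical(cfg)
  truth1 <- coh$truth
  truth1$true_suppression <- rep(0, nrow(coh$records))
  s <- gen_clamp(coh$records[1, , drop = FALSE],
                 local({t <- truth1; t$true_suppression <- t$true_suppression[1]; t}),
                 cfg)[[1]]
  p <- attr(s, "true_params")
  e_expected <- p$f_inf / (p$ra_basal + p$f_inf)
  expect_lt(abs(s$enrich[nrow(s)] - e_expected) / e_expected, 1e-6)
})

test_that("clamp forward model conserves tracer mass and matches an ODE solver", {
  prof <- metsynflux:::one_pool_profile(
    times = seq(-120, 240, by = 1), f_inf = 0.1, volume = 0.23,
    c_basal = 80, ra_basal = 2.5, supp_pct = 68.1, t_half = 30
  )
  p <- prof$params
  # mass balance: d(q_tr)/dt = F - E * (k * q_tot) at every interior point
  t <- seq(-100, 240, by = 0.5)
  qt <- prof$q_tr(t)
  qe <- prof$q_ee(t)
  h <- 1e-3
  dqt <- (prof$q_tr(t + h) - prof$q_tr(t - h)) / (2 * h)
  expect_lt(max(abs(dqt - (p$f_inf - (qt / (qt + qe)) * p$k * (qt + qe)))), 1e-6)

  # independent numerical integration of the same model
  rhs <- function(time, state, parms) {
    ra <- if (time <= 0) p$ra_basal else {
      p$ra_inf + (p$ra_basal - p$ra_inf) * exp(-p$lambda * time)
    }
    list(c(
      ra - p$k * state[1],
      p$f_inf - p$k * state[2]
    ))
  }
  ode_t <- c(-120, 0, 60, 120, 240)
  out <- deSolve::lsoda(
    y = c(q_ee = p$ra_basal / p$k, q_tr = 0), times = ode_t, func = rhs,
    parms = NULL, rtol = 1e-10, atol = 1e-12
  )
  expect_equal(unname(out[, "q_ee"]), prof$q_ee(ode_t), tolerance = 1e-6)
  expect_equal(unname(out[, "q_tr"]), prof$q_tr(ode_t), tolerance = 1e-6)
})

test_that("cohort artifacts round-trip through their plain-text formats", {
  cfg <- sim_config(n_subjects = 12, n_metabolites = 25,
                    ir_effect_metabolites = 1:3, fram_effect_metabolites = 4:6)
  coh <- gen_clinical(cfg)
  tab <- gen_metabolites(coh$records, coh$truth, cfg)
  cl <- gen_clamp(coh$records[1:3, ],
                  local({t <- coh$truth; t$true_suppression <- t$true_suppression[1:3]; t}),
                  cfg)
  d <- withr::local_tempdir()
  write_clinical_csv(coh$records, file.path(d, "clin.csv"))
  rec2 <- read_clinical_csv(file.path(d, "clin.csv"))
  expect_equal(rec2$bmi, coh$records$bmi, tolerance = 1e-12)
  write_metabolite_tsv(tab, file.path(d, "ab.tsv"), file.path(d, "ann.tsv"))
  tab2 <- read_metabolite_tsv(file.path(d, "ab.tsv"), file.path(d, "ann.tsv"))
  expect_equal(tab2$abundances, tab$abundances, tolerance = 1e-12)
  expect_identical(tab2$annotations$superpathway, tab$annotations$superpathway)
  write_clamp_csv(cl, file.path(d, "clamp.csv"))
  cl2 <- read_clamp_csv(file.path(d, "clamp.csv"))
  expect_equal(cl2[[1]]$enrich, cl[[1]]$enrich, tolerance = 1e-12)
  expect_identical(names(cl2), names(cl))
})
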