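# helper: noise-free single-subject clamp series at a given true suppression
sim_series <- function(supp, times = NULL, seed = 5) {
  clamp <- if (is.null(times)) list() else list(times = times)
  cfg <- sim_config(seed = seed, clamp_true_suppression = supp,
                    clamp_noise_cv = 0, supp_insulin_slope = 0, supp_sd = 0,
                    clamp = clamp)
  coh <- gen_clinical(cfg)
  truth <- coh$truth
  truth$true_suppression <- truth$true_suppression[1]
  gen_clamp(coh$records[1, , drop = FALSE], truth, cfg)[[1]]
}

test_that("steady-state Steele estimate follows tracer dilution", {
  expect_equal(steele_steady(0.1, 0.01), 9.9)
  expect_equal(steele_steady(0.1, 0.5), 0.1)
  expect_equal(steele_steady(0.1, 0.5, correct_tracer = FALSE), 0.2)
  expect_error(steele_steady(0.1, 0), "enrichment")
  expect_error(steele_steady(0.1, 1), "enrichment")
  expect_error(steele_steady(0, 0.1), "positive")
})

test_that("steady-state estimate recovers true Ra from an equilibrated pool", {
  s <- sim_series(0, times = c(-30, -15, 0, 600, 900, 901))
  p <- attr(s, "true_params")
  est <- steele_steady(s$f_inf[nrow(s)], s$enrich[nrow(s)])
  expect_lt(abs(est - p$ra_basal) / p$ra_basal, 1e-6)
})

test_that("non-steady-state estimator reduces exactly to the steady form", {
  s <- clamp_series("a", time = c(0, 10), phase = "step1",
                    f_inf = 0.1, conc = c(80, 80), enrich = c(0.01, 0.01))
  out <- steele_nonsteady(s, steele_params(p = 0.65, volume = 0.23))
  expect_equal(out$ra, 9.9)
  expect_equal(out$rd, 9.9)
  expect_identical(out$ra, steele_steady(0.1, 0.01))
})

test_that("windowed non-steady estimates track the true declining Ra", {
  s <- sim_series(68.1, times = seq(-30, 240, by = 5))
  est <- steele_nonsteady(s[s$time >= 0, ], steele_params(p = 1, volume = 0.23))
  truth <- vapply(seq_len(nrow(est)), function(i) {
    true_ra_mean(s, est$t_start[i], est$t_end[i])
  }, numeric(1))
  expect_lt(max(abs(est$ra - truth) / truth), 0.05)
})

test_that("suppression components satisfy the defining identity and monotonicity", {
  est <- estimate_suppression(sim_series(68.1))
  expect_equal(est$ra_supp,
               100 * (est$ra_basal - est$ra_clamp) / est$ra_basal)
  # strictly decreasing in ra_clamp for fixed ra_basal
  supp_grid <- c(0, 25, 50, 68.1, 90)
  ests <- lapply(supp_grid, function(s) estimate_suppression(sim_series(s)))
  ra_clamp <- vapply(ests, `[[`, numeric(1), "ra_clamp")
  ra_supp <- vapply(ests, `[[`, numeric(1), "ra_supp")
  expect_true(all(diff(ra_clamp) < 0))
  expect_true(all(diff(ra_supp) > 0))
  # zero suppression estimates near zero
  expect_lt(abs(ests[[1]]$ra_supp), 2)
})

test_that("suppression estimation errors on unusable series", {
  s <- sim_series(50)
  no_basal <- s[s$phase != "basal", ]
  expect_error(estimate_suppression(no_basal), "basal")
  one_step <- s[s$time <= 30, ]
  expect_error(estimate_suppression(one_step), "step1")
})

test_that("series and parameter constructors reject invalid physical values", {
  expect_error(clamp_series("a", c(0, 0), "basal", 0.1, c(80, 80), c(0.01, 0.01)),
               "increasing")
  expect_error(clamp_series("a", c(0, 10), "basal", 0.1, c(80, -1), c(0.01, 0.01)),
               "positive")
  expect_error(clamp_series("a", c(0, 10), "basal", 0.1, c(80, 80), c(0.01, 1.2)),
               "\\(0, 1\\)")
  expect_error(clamp_series("a", c(0, 10), "basal", -0.1, c(80, 80), c(0.01, 0.01)),
               ">= 0")
  expect_error(steele_params(p = 0), "\\(0, 1\\]")
  expect_error(steele_params(volume = -1), "> 0")
})

test_that("insulin resistance classification applies the Rd 37.3 cutoff", {
  expect_equal(classify_ir(27), "IR")
  expect_equal(classify_ir(37.3), "N-IR")  # boundary belongs to N-IR
  expect_equal(classify_ir(48.1), "N-IR")
  expect_equal(classify_ir(c(10, 50)), c("IR", "N-IR"))
  expect_error(classify_ir(NaN), "finite")
})

test_that("negative non-steady estimates are flagged, not clipped", {
  s <- clamp_series("a", time = c(0, 10), phase = "step1", f_inf = 0.1,
                    conc = c(80, 80), enrich = c(0.01, 0.2))
  expect_warning(out <- steele_nonsteady(s, steele_params(p = 1, volume = 0.23)),
                 "negative")
  expect_lt(out$ra, 0)
  expect_true(out$negative)
})
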