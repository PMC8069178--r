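small_cv <- function(n_iterations = 5, top_k = 10, base_seed = 3) {
  cv_config(
    n_iterations = n_iterations, grid = cv_reduced_grid(),
    base_seed = base_seed, top_k = top_k, learner_params = fast_learner
  )
}

noise_xy <- function(n = 60, p = 30, seed = 2) {
  set.seed(seed)
  x <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, sprintf("f%02d", 1:p)))
  y <- rep(c(0, 1), length.out = n)
  list(x = x, y = y)
}

test_that("a near-perfect predictor dominates AUC and importance", {
  d <- noise_xy(n = 100)
  d$x[, 7] <- d$y + rnorm(100, sd = 0.01)
  res <- run_nested_cv(d$x, d$y, small_cv())
  expect_gt(res$mean_auc, 0.95)
  expect_equal(res$top_features[1], "f07")
})

test_that("the harness is bit-reproducible and self-consistent", {
  d <- noise_xy(seed = 5)
  r1 <- run_nested_cv(d$x, d$y, small_cv())
  r2 <- run_nested_cv(d$x, d$y, small_cv())
  expect_identical(r1$per_iteration_auc, r2$per_iteration_auc)
  expect_identical(r1$feature_importance, r2$feature_importance)
  expect_true(all(r1$per_iteration_auc >= 0 & r1$per_iteration_auc <= 1))
  expect_equal(r1$mean_auc, mean(r1$per_iteration_auc))
  expect_equal(r1$sd_auc, sd(r1$per_iteration_auc))
  expect_length(r1$per_iteration_auc, 5)
})

test_that("hyperparameter choice never depends on the test split", {
  d <- noise_xy(seed = 9)
  cfg <- small_cv(n_iterations = 1)
  r1 <- run_nested_cv(d$x, d$y, cfg)
  x2 <- d$x
  # corrupt the features of the test split; training data untouched
  idx <- r1$test_indices[[1]]
  x2[idx, ] <- x2[idx, ] * 100 + 7
  r2 <- run_nested_cv(x2, d$y, cfg)
  expect_identical(r1$test_indices, r2$test_indices)
  for (col in c("max_depth", "eta", "nrounds", "subsample", "inner_auc")) {
    expect_identical(r1$chosen_params[[col]], r2$chosen_params[[col]])
  }
  # the test AUC, by contrast, does change
  expect_false(identical(r1$per_iteration_auc, r2$per_iteration_auc))
})

test_that("label-independent features give chance-level AUC", {
  d <- noise_xy(n = 80, p = 40, seed = 13)
  res <- run_nested_cv(d$x, d$y, small_cv(n_iterations = 8))
  expect_gt(res$mean_auc, 0.25)
  expect_lt(res$mean_auc, 0.75)
})

test_that("top-feature selection applies the documented tie-break", {
  fake <- structure(list(feature_importance = data.frame(
    feature = c("b", "a", "c", "d", "sanity_1"),
    importance = c(0.3, 0.3, 0.5, 0.1, 0.9),
    frequency = c(0.2, 0.9, 1.0, 0.1, 1.0),
    is_sanity = c(FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )), class = "nested_cv_result")
  # independent sort oracle: importance desc, then frequency desc, then id
  oracle <- with(
    fake$feature_importance[!fake$feature_importance$is_sanity, ],
    feature[order(-importance, -frequency, feature)]
  )
  expect_identical(select_top_features(fake, 4), oracle)
  expect_identical(select_top_features(fake, 2), c("c", "a"))
  expect_identical(select_top_features(fake, 0), character(0))
  expect_error(select_top_features(fake, 5), "exceeds")
})

test_that("subset reruns restrict the matrix and keep the protocol", {
  d <- noise_xy(seed = 17)
  d$x[, 3] <- d$y + rnorm(60, sd = 0.01)
  res <- rerun_on_subset(d$x, d$y, "f03", small_cv(n_iterations = 3))
  expect_gt(res$mean_auc, 0.95)
  expect_error(rerun_on_subset(d$x, d$y, "nope", small_cv()), "not in x")
})

test_that("sanity probes behave under null and disabled configurations", {
  d <- noise_xy(n = 80, p = 40, seed = 23)
  cfg0 <- small_cv(n_iterations = 4)
  cfg0$n_sanity_features <- 0L
  r0 <- run_nested_cv(d$x, d$y, cfg0)
  expect_equal(sanity_report(r0)$fraction, 0)
  # pure noise: probes exchangeable with real features, so they enter the
  # per-iteration top-k at roughly k * n_sanity / (p + n_sanity)
  r <- run_nested_cv(d$x, d$y, small_cv(n_iterations = 10))
  per_iter_rate <- 1 - (1 - 10 / 42)^2
  expect_lt(abs(sanity_report(r)$fraction - per_iter_rate), 0.4)
})

test_that("degenerate inputs are rejected with informative errors", {
  d <- noise_xy()
  expect_error(run_nested_cv(d$x, rep(1, 60), small_cv()), "0/1|two")
  expect_error(run_nested_cv(d$x[1:6, ], d$y[1:6], small_cv()), "10")
  xna <- d$x; xna[1, 1] <- NA
  expect_error(run_nested_cv(xna, d$y, small_cv()), "missing")
  y_rare <- c(rep(0, 57), rep(1, 3))
  expect_error(run_nested_cv(d$x, y_rare, small_cv()), "inner_folds")
})
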