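#' Default hyperparameter grid for the boosted-tree learner
#'
#' Tree depth, learning rate, number of boosting rounds, and row
#' subsampling; 54 combinations searched by inner cross-validation.
#' @return Data frame of grid rows.
#' @export
cv_default_grid <- function() {
  expand.grid(
    max_depth = c(2, 3, 4), eta = c(0.05, 0.1, 0.3),
    nrounds = c(50, 100, 200), subsample = c(0.8, 1.0),
    KEEP.OUT.ATTRS = FALSE
  )
}

#' Reduced hyperparameter grid
#'
#' A two-point grid (tree depth 2 or 3, learning rate 0.3, 30 rounds,
#' 80% subsampling) for simulation studies where the full grid is not
#' affordable; at cohort sizes around n = 132 it reaches essentially the
#' same test AUC as the full grid.
#' @return Data frame of grid rows.
#' @export
cv_reduced_grid <- function() {
  expand.grid(
    max_depth = c(2, 3), eta = 0.3, nrounds = 30, subsample = 0.8,
    KEEP.OUT.ATTRS = FALSE
  )
}

#' Nested cross-validation configuration
#'
#' @param n_iterations Outer train/test resampling iterations. Default 100.
#' @param test_fraction Held-out fraction per iteration. Default 0.20.
#' @param inner_folds Inner CV folds for hyperparameter tuning. Default 5.
#' @param n_sanity_features Random standard-normal probe columns appended
#'   each iteration. Default 2.
#' @param top_k Size of the reported top-feature set. Default 20.
#' @param grid Hyperparameter grid (data frame with columns `max_depth`,
#'   `eta`, `nrounds`, `subsample`). Default [cv_default_grid()].
#' @param base_seed Seed; iteration i uses `base_seed + i`. Default 1.
#' @param learner_params Fixed xgboost parameters (histogram method,
#'   coarse 32-level bins — ample for cohort-scale sample counts — and a
#'   single thread for reproducibility).
#' @return A list of class `cv_config`.
#' @export
cv_config <- function(n_iterations = 100, test_fraction = 0.2, inner_folds = 5,
                      n_sanity_features = 2, top_k = 20,
                      grid = cv_default_grid(), base_seed = 1,
                      learner_params = list(tree_method = "hist", max_bin = 32,
                                            nthread = 1)) {
  if (test_fraction <= 0 || test_fraction >= 1) stop("test_fraction must lie in (0, 1)")
  if (inner_folds < 2) stop("inner_folds must be >= 2")
  if (n_iterations < 1) stop("n_iterations must be >= 1")
  if (n_sanity_features < 0) stop("n_sanity_features must be >= 0")
  need <- c("max_depth", "eta", "nrounds", "subsample")
  if (!all(need %in% names(grid))) {
    stop("grid needs columns: ", paste(need, collapse = ", "))
  }
  structure(
    list(
      n_iterations = as.integer(n_iterations), test_fraction = test_fraction,
      inner_folds = as.integer(inner_folds),
      n_sanity_features = as.integer(n_sanity_features),
      top_k = as.integer(top_k), grid = grid,
      base_seed = as.integer(base_seed), learner_params = learner_params
    ),
    class = "cv_config"
  )
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC with average ranks for tied scores.
#'
#' @param scores Numeric classifier scores.
#' @param labels Binary labels (logical, 0/1, or two-level factor;
#'   positive class is TRUE / 1 / the second level).
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  y <- as_binary_labels(labels)
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) stop("both classes required to compute AUC")
  r <- rank(scores)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

as_binary_labels <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels) || is.character(labels)) {
    lev <- if (is.factor(labels)) levels(droplevels(as.factor(labels))) else sort(unique(labels))
    if (length(lev) != 2) stop("labels must have exactly two classes")
    return(as.integer(as.character(labels) == lev[2]))
  }
  u <- sort(unique(labels))
  if (!all(u %in% c(0, 1)) || length(u) != 2) {
    stop("numeric labels must be 0/1 with both classes present")
  }
  as.integer(labels)
}

# index split preserving class proportions
stratified_split <- function(y, test_fraction) {
  test <- integer(0)
  for (cls in unique(y)) {
    idx <- which(y == cls)
    n_test <- max(1L, round(test_fraction * length(idx)))
    if (n_test >= length(idx)) stop("class too small for the requested split")
    test <- c(test, sample(idx, n_test))
  }
  list(train = setdiff(seq_along(y), test), test = sort(test))
}

# per-class balanced fold assignment
stratified_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

fit_boosted <- function(x, y, row, learner_params) {
  dtrain <- xgboost::xgb.DMatrix(x, label = y)
  params <- c(
    list(
      objective = "binary:logistic",
      max_depth = row$max_depth, eta = row$eta, subsample = row$subsample
    ),
    learner_params
  )
  xgboost::xgb.train(params = params, data = dtrain, nrounds = row$nrounds,
                     verbose = 0)
}

# gain-based importance mapped onto the full feature set (0 when unused)
gain_importance <- function(model, feature_names) {
  imp <- xgboost::xgb.importance(model = model)
  out <- stats::setNames(numeric(length(feature_names)), feature_names)
  if (!is.null(imp) && nrow(imp)) out[imp$Feature] <- imp$Gain
  s <- sum(out)
  if (s > 0) out <- out / s
  out
}

# top-k names among features with positive importance, ties broken by
# descending value then name; fewer than k when fewer were used at all
topk_names <- function(imp, k) {
  imp <- imp[imp > 0]
  names(imp)[order(-imp, names(imp))][seq_len(min(k, length(imp)))]
}

#' Nested cross-validated boosted-tree classification
#'
#' The protocol: in each of `n_iterations` iterations (seeded
#' `base_seed + i`), `n_sanity_features` fresh standard-normal probe
#' columns are appended to the predictors, the cohort is split into a
#' stratified 80/20 train/test partition, hyperparameters are chosen by
#' inner stratified `inner_folds`-fold cross-validation on the training
#' split (maximizing held-out AUC; ties resolved in grid order), the
#' winning configuration is refit on the whole training split, and the
#' test-split AUC and gain-based feature importances are recorded.
#' Importances are aggregated as the mean over iterations, together with
#' each feature's selection frequency (fraction of iterations it entered
#' the per-iteration top `top_k`).
#'
#' Hyperparameter selection never sees the test split, so permuting test
#' labels cannot change the chosen configuration.
#'
#' @param x Numeric feature matrix (samples x features), no missing
#'   values; column names are feature ids.
#' @param y Binary labels (see [auc_score()] for accepted encodings).
#' @param config A [cv_config()].
#' @return Object of class `nested_cv_result`: `per_iteration_auc`,
#'   `mean_auc`, `sd_auc`, `feature_importance` (data frame: `feature`,
#'   `importance`, `frequency`, `is_sanity`), `sanity_flags`,
#'   `top_features`, `chosen_params`, `test_indices`, `config`.
#' @export
run_nested_cv <- function(x, y, config = cv_config()) {
  stopifnot(inherits(config, "cv_config"))
  x <- as.matrix(x)
  if (!is.numeric(x)) stop("x must be numeric")
  if (any(is.na(x))) stop("x must not contain missing values")
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%04d", seq_len(ncol(x)))
  y <- as_binary_labels(y)
  if (length(y) != nrow(x)) stop("y must match rows of x")
  if (nrow(x) < 10) stop("need at least 10 samples")
  if (min(table(y)) < config$inner_folds) {
    stop("each class needs at least inner_folds samples")
  }
  if (config$top_k > ncol(x)) stop("top_k exceeds the number of real features")
  sanity_names <- if (config$n_sanity_features > 0) {
    paste0("sanity_", seq_len(config$n_sanity_features))
  } else character(0)
  if (any(sanity_names %in% colnames(x))) {
    stop("feature names clash with reserved sanity feature names")
  }
  all_names <- c(colnames(x), sanity_names)
  grid <- config$grid

  n_iter <- config$n_iterations
  aucs <- numeric(n_iter)
  sanity_flags <- logical(n_iter)
  imp_sum <- stats::setNames(numeric(length(all_names)), all_names)
  topk_count <- imp_sum
  chosen <- vector("list", n_iter)
  test_indices <- vector("list", n_iter)

  for (i in seq_len(n_iter)) {
    set.seed(config$base_seed + i)
    xs <- if (length(sanity_names)) {
      cbind(x, matrix(stats::rnorm(nrow(x) * length(sanity_names)),
                      nrow(x), length(sanity_names),
                      dimnames = list(NULL, sanity_names)))
    } else x
    split <- stratified_split(y, config$test_fraction)
    x_tr <- xs[split$train, , drop = FALSE]
    y_tr <- y[split$train]

    fold <- stratified_folds(y_tr, config$inner_folds)
    grid_auc <- numeric(nrow(grid))
    for (g in seq_len(nrow(grid))) {
      fold_auc <- numeric(config$inner_folds)
      for (f in seq_len(config$inner_folds)) {
        hold <- fold == f
        m <- fit_boosted(x_tr[!hold, , drop = FALSE], y_tr[!hold],
                         grid[g, ], config$learner_params)
        p <- stats::predict(m, xgboost::xgb.DMatrix(x_tr[hold, , drop = FALSE]))
        fold_auc[f] <- auc_score(p, y_tr[hold])
      }
      grid_auc[g] <- mean(fold_auc)
    }
    best <- which.max(grid_auc)  # first maximum = earliest grid row

    m <- fit_boosted(x_tr, y_tr, grid[best, ], config$learner_params)
    p_test <- stats::predict(m, xgboost::xgb.DMatrix(xs[split$test, , drop = FALSE]))
    aucs[i] <- auc_score(p_test, y[split$test])

    imp <- gain_importance(m, all_names)
    imp_sum <- imp_sum + imp
    tk <- topk_names(imp, config$top_k)
    topk_count[tk] <- topk_count[tk] + 1
    sanity_flags[i] <- any(tk %in% sanity_names)
    chosen[[i]] <- cbind(iteration = i, grid[best, , drop = FALSE],
                         inner_auc = grid_auc[best])
    test_indices[[i]] <- split$test
  }

  fi <- data.frame(
    feature = all_names,
    importance = unname(imp_sum) / n_iter,
    frequency = unname(topk_count) / n_iter,
    is_sanity = all_names %in% sanity_names,
    stringsAsFactors = FALSE
  )
  res <- structure(
    list(
      per_iteration_auc = aucs,
      mean_auc = mean(aucs),
      sd_auc = stats::sd(aucs),
      feature_importance = fi,
      sanity_flags = sanity_flags,
      top_features = NULL,
      chosen_params = do.call(rbind, chosen),
      test_indices = test_indices,
      config = config
    ),
    class = "nested_cv_result"
  )
  res$top_features <- select_top_features(res, config$top_k)
  res
}

#' @export
print.nested_cv_result <- function(x, ...) {
  cat(sprintf(
    "nested_cv_result: %d iterations, AUC = %.2f +/- %.2f\n",
    length(x$per_iteration_auc), x$mean_auc, x$sd_auc
  ))
  cat("top features:", paste(utils::head(x$top_features, 10), collapse = ", "),
      if (length(x$top_features) > 10) "..." else "", "\n")
  sr <- sanity_report(x)
  cat(sprintf("sanity features in per-iteration top-k: %.0f%% of iterations\n",
              100 * sr$fraction))
  invisible(x)
}

#' Top-k real features by aggregated importance
#'
#' Ranks non-sanity features by mean importance, breaking ties by
#' descending selection frequency and then by feature id.
#'
#' @param result A `nested_cv_result`.
#' @param k Number of features to return.
#' @return Character vector of length `k`.
#' @export
select_top_features <- function(result, k) {
  stopifnot(inherits(result, "nested_cv_result"))
  fi <- result$feature_importance[!result$feature_importance$is_sanity, ]
  if (k > nrow(fi)) stop("k exceeds the number of real features")
  if (k == 0) return(character(0))
  fi <- fi[order(-fi$importance, -fi$frequency, fi$feature), ]
  fi$feature[seq_len(k)]
}

#' Re-run the nested CV protocol on a feature subset
#'
#' Identical protocol on the restricted matrix (typically the top-k
#' features of a previous run); sanity features are appended afresh.
#'
#' @param x,y,config As in [run_nested_cv()].
#' @param features Subset of `colnames(x)` to keep.
#' @return A `nested_cv_result`.
#' @export
rerun_on_subset <- function(x, y, features, config = cv_config()) {
  x <- as.matrix(x)
  if (is.null(colnames(x))) colnames(x) <- sprintf("f%04d", seq_len(ncol(x)))
  missing <- setdiff(features, colnames(x))
  if (length(missing)) {
    stop("features not in x: ", paste(utils::head(missing, 5), collapse = ", "))
  }
  cfg <- config
  cfg$top_k <- min(config$top_k, length(features))
  run_nested_cv(x[, features, drop = FALSE], y, cfg)
}

#' Sanity-feature report
#'
#' Fraction of iterations in which any random probe column entered the
#' per-iteration top-k importances. On data with real signal this should
#' be rare; a fraction above 5% warns that reported importances are not
#' trustworthy.
#'
#' @param result A `nested_cv_result`.
#' @return List with `fraction`, `n_iterations`, `warn`.
#' @export
sanity_report <- function(result) {
  stopifnot(inherits(result, "nested_cv_result"))
  fraction <- mean(result$sanity_flags)
  list(
    fraction = fraction,
    n_iterations = length(result$sanity_flags),
    warn = fraction > 0.05
  )
}
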