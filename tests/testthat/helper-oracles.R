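# Independent oracles used across the suite. These deliberately avoid the
# code paths they check.

# Two-sided Mann-Whitney p by exhaustive enumeration of all C(n+m, n)
# label assignments; symmetric-tail definition. Valid for untied data.
enumerate_mw_p <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  m <- length(y)
  u_of <- function(xs, ys) sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  u_obs <- u_of(x, y)
  mu <- n * m / 2
  combs <- utils::combn(n + m, n)
  us <- apply(combs, 2, function(idx) u_of(pooled[idx], pooled[-idx]))
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Brute-force Benjamini-Hochberg step-up: q(i) = min_{j >= i} p_(j) m / j,
# capped at 1, mapped back to input order.
brute_force_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  q_sorted <- vapply(seq_len(m), function(i) {
    min(1, min(sorted[i:m] * m / (i:m)))
  }, numeric(1))
  q <- numeric(m)
  q[o] <- q_sorted
  q
}

# Pooled within-group SD (the planted-effect standardization scale).
pooled_sd <- function(x, g) {
  v <- tapply(x, g, stats::var)
  n <- tapply(x, g, length)
  sqrt(sum((n - 1) * v) / (sum(n) - length(v)))
}

# Small planted-effect cohort used by several tests.
make_cohort <- function(seed = 1, n_metabolites = 150, ...) {
  cfg <- sim_config(seed = seed, n_metabolites = n_metabolites, ...)
  coh <- gen_clinical(cfg)
  tab <- gen_metabolites(coh$records, coh$truth, cfg)
  list(config = cfg, records = coh$records, truth = coh$truth,
       table = preprocess_table(tab), raw = tab)
}

fast_learner <- list(tree_method = "hist", max_bin = 16, nthread = 1)

# Shared cache so the expensive planted-recovery simulation is computed
# once and reused by the tests that assess different aspects of it.
.sim_cache <- new.env(parent = emptyenv())

planted_recovery_runs <- function(n_cohorts = 10, n_iterations = 100) {
  key <- sprintf("planted_%d_%d", n_cohorts, n_iterations)
  if (!is.null(.sim_cache[[key]])) return(.sim_cache[[key]])
  planted_ids <- sprintf("M%04d", 1:14)
  res <- lapply(seq_len(n_cohorts), function(r) {
    cfg <- sim_config(seed = 100 + r)
    coh <- gen_clinical(cfg)
    tab <- preprocess_table(gen_metabolites(coh$records, coh$truth, cfg))
    cv <- cv_config(
      n_iterations = n_iterations, grid = cv_reduced_grid(),
      base_seed = 100 + r, learner_params = fast_learner
    )
    all_run <- run_nested_cv(tab$abundances, coh$truth$is_ir, cv)
    top_run <- rerun_on_subset(tab$abundances, coh$truth$is_ir,
                               all_run$top_features, cv)
    list(
      n_planted_top20 = sum(all_run$top_features %in% planted_ids),
      auc_all = all_run$mean_auc,
      auc_top = top_run$mean_auc,
      sanity_fraction = sanity_report(all_run)$fraction
    )
  })
  .sim_cache[[key]] <- res
  res
}
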