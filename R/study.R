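#' Intersect top machine-learning features with univariate screen hits
#'
#' Returns the metabolites that are both among the harness's top features
#' and significant in the univariate screen at `alpha_q`, ordered by
#' ascending screen q-value.
#'
#' @param top_features Character vector of metabolite ids.
#' @param screen A screen result data frame ([screen_groups()] /
#'   [screen_correlation()]).
#' @param alpha_q Significance threshold on q-values. Default 0.05.
#' @return Character vector of overlapping metabolite ids.
#' @export
overlap_features <- function(top_features, screen, alpha_q = 0.05) {
  unknown <- setdiff(top_features, screen$metabolite_id)
  if (length(unknown)) {
    stop("feature namespace mismatch; not in screen: ",
         paste(utils::head(unknown, 5), collapse = ", "))
  }
  hits <- screen[!is.na(screen$q_value) & screen$q_value < alpha_q, ]
  hits <- hits[hits$metabolite_id %in% top_features, ]
  hits$metabolite_id[order(hits$q_value)]
}

#' Lipolysis (Ra suppression) correlation analyses
#'
#' Runs the three Ra-suppression correlation surfaces on the clamp
#' subset: a Spearman screen of all metabolites vs percent suppression
#' (FDR within the full panel), the same screen restricted to the lipid
#' superpathway (FDR within that smaller family — a metabolite can be
#' significant here yet not in the full-panel family), and Spearman
#' correlations of eight clinical parameters (HOMA-IR, fasting insulin,
#' fasting glucose, LDL, HDL, BMI, age, triglycerides) vs suppression
#' with FDR within the clinical family alone.
#'
#' @param table A preprocessed [metabolite_table()] covering (at least)
#'   the clamp subjects.
#' @param suppression Data frame with `subject_id` and `ra_supp`.
#' @param clinical Clinical records covering the clamp subjects.
#' @param lipid_superpathway Superpathway label defining the lipid
#'   family. Default "Lipid".
#' @param alpha_q Significance threshold. Default 0.05.
#' @return List with `all_screen`, `lipid_screen`, `clinical_correlates`,
#'   `n_subjects`.
#' @export
lipolysis_analysis <- function(table, suppression, clinical,
                               lipid_superpathway = "Lipid", alpha_q = 0.05) {
  stopifnot(inherits(table, "metabolite_table"))
  ids <- suppression$subject_id
  if (!all(ids %in% table$sample_ids)) {
    stop("suppression subjects missing from the metabolite table")
  }
  if (!all(ids %in% clinical$subject_id)) {
    stop("suppression subjects missing from the clinical records")
  }
  sub <- subset_table(table, samples = ids)
  all_screen <- screen_correlation(sub, suppression$ra_supp, alpha_q)
  lipid_ids <- sub$annotations$metabolite_id[
    sub$annotations$superpathway == lipid_superpathway
  ]
  if (!length(lipid_ids)) stop("empty lipid family: no metabolites annotated ",
                               lipid_superpathway)
  lipid_screen <- screen_correlation(
    subset_table(sub, metabolites = lipid_ids), suppression$ra_supp, alpha_q
  )
  cl <- clinical[match(ids, clinical$subject_id), ]
  params <- list(
    homa_ir = homa_ir(cl$fasting_glucose, cl$fasting_insulin),
    insulin = cl$fasting_insulin,
    glucose = cl$fasting_glucose,
    ldl = cl$ldl, hdl = cl$hdl, bmi = cl$bmi, age = cl$age,
    triglycerides = cl$triglycerides
  )
  rows <- lapply(names(params), function(p) {
    ht <- spearman_rho(params[[p]], suppression$ra_supp)
    data.frame(parameter = p, rho = ht$rho, p_value = ht$p_value,
               stringsAsFactors = FALSE)
  })
  clinical_correlates <- do.call(rbind, rows)
  clinical_correlates$q_value <- bh_fdr(clinical_correlates$p_value)
  clinical_correlates$significant <-
    !is.na(clinical_correlates$q_value) & clinical_correlates$q_value < alpha_q
  list(
    all_screen = all_screen, lipid_screen = lipid_screen,
    clinical_correlates = clinical_correlates, n_subjects = length(ids)
  )
}

#' Run the full study replica on a synthetic cohort
#'
#' End-to-end pipeline: generate the cohort (clinical records, metabolite
#' table, clamp series for a subset), preprocess abundances (median
#' rescale, half-minimum imputation), estimate per-subject lipolysis
#' suppression from the clamp tracer data, classify peripheral insulin
#' resistance from Rd, compute Framingham risks and dichotomize at the
#' cutoff, screen metabolites against IR status and against the risk
#' score, run the nested-CV boosted-tree classifier of high vs low risk
#' on all metabolites and again on its top-k features, intersect top
#' features with the risk correlates, and run the lipolysis correlation
#' analyses. Every stochastic stage is seeded from the master seed, so a
#' repeated run is bit-identical.
#'
#' @param config A [sim_config()] describing the cohort.
#' @param cv A [cv_config()] for the classification harness.
#' @param out_dir Optional directory; when given, all result tables and a
#'   `summary.json` are written there.
#' @param seed Optional master seed overriding `config$seed` and
#'   `cv$base_seed`.
#' @param n_clamp Number of subjects in the clamp (lipolysis) subset.
#'   Default 39.
#' @param rd_cutoff IR classification threshold (umol/kg/min). Default 37.3.
#' @param fram_cutoff Framingham dichotomization cutoff (%). Default 12.
#' @param alpha_q FDR significance threshold. Default 0.05.
#' @return A list of class `study_report`; see Details for components.
#' @export
run_study <- function(config = sim_config(), cv = cv_config(), out_dir = NULL,
                      seed = NULL, n_clamp = 39, rd_cutoff = 37.3,
                      fram_cutoff = 12, alpha_q = 0.05) {
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
    cv$base_seed <- as.integer(seed) + 5000L
  }
  cohort <- gen_clinical(config)
  records <- cohort$records
  truth <- cohort$truth
  if (nrow(records) == 0) stop("empty cohort; increase n_subjects")
  table_raw <- gen_metabolites(records, truth, config)
  table_pp <- preprocess_table(table_raw)

  # clamp subset and suppression estimates
  n_clamp <- min(n_clamp, nrow(records))
  set.seed(config$seed + 3L)
  clamp_idx <- sort(sample.int(nrow(records), n_clamp))
  clamp_truth <- truth
  clamp_truth$true_suppression <- truth$true_suppression[clamp_idx]
  series <- gen_clamp(records[clamp_idx, ], clamp_truth, config)
  supp_rows <- lapply(series, function(s) {
    est <- estimate_suppression(
      s, steele_params(volume = config$clamp$volume)
    )
    data.frame(subject_id = s$subject_id[1], ra_basal = est$ra_basal,
               ra_clamp = est$ra_clamp, ra_supp = est$ra_supp,
               stringsAsFactors = FALSE)
  })
  suppression <- do.call(rbind, supp_rows)
  rownames(suppression) <- NULL

  # insulin resistance and CVD risk
  ir_labels <- classify_ir(records$rd, rd_cutoff)
  risk <- framingham_risk(records)
  fram_groups <- dichotomize_framingham(risk, fram_cutoff)

  # univariate surfaces
  ir_screen <- screen_groups(table_pp, ir_labels, alpha_q)
  fram_correlates <- screen_correlation(table_pp, risk, alpha_q)

  # nested-CV classification of high vs low Framingham risk
  x <- table_pp$abundances
  y <- fram_groups == "high"
  ml_all <- run_nested_cv(x, y, cv)
  ml_top <- rerun_on_subset(x, y, ml_all$top_features, cv)
  overlap <- overlap_features(ml_all$top_features, fram_correlates, alpha_q)

  lipolysis <- lipolysis_analysis(table_pp, suppression, records,
                                  alpha_q = alpha_q)

  report <- structure(
    list(
      records = records, truth = truth, table = table_pp,
      suppression = suppression, ir_labels = ir_labels, risk = risk,
      fram_groups = fram_groups, ir_screen = ir_screen,
      fram_correlates = fram_correlates, ml_all = ml_all,
      ml_top = ml_top, overlap = overlap, lipolysis = lipolysis,
      settings = list(
        seed = config$seed, n_clamp = n_clamp, rd_cutoff = rd_cutoff,
        fram_cutoff = fram_cutoff, alpha_q = alpha_q,
        top_k = cv$top_k, n_iterations = cv$n_iterations
      )
    ),
    class = "study_report"
  )
  if (!is.null(out_dir)) write_study_report(report, out_dir)
  report
}

#' @export
print.study_report <- function(x, ...) {
  s <- study_summary(x)
  cat(sprintf(
    paste0(
      "study_report: %d subjects, %d metabolites, clamp subset n = %d\n",
      "  IR: %d subjects (Rd < %.1f); IR screen hits (q < %.2f): %d\n",
      "  Framingham: median %.1f%%, high-risk n = %d; correlates: %d\n",
      "  median Ra suppression: %.1f%%\n",
      "  AUC all features %.2f +/- %.2f; top-%d %.2f +/- %.2f; overlap %d\n"
    ),
    s$n_subjects, s$n_metabolites, s$n_clamp,
    s$n_ir, x$settings$rd_cutoff, x$settings$alpha_q, s$ir_screen_hits,
    s$median_framingham, s$n_high_framingham, s$fram_correlates,
    s$median_ra_supp,
    s$auc_all_mean, s$auc_all_sd, x$settings$top_k,
    s$auc_top_mean, s$auc_top_sd, s$overlap_size
  ))
  invisible(x)
}

#' Compact numeric summary of a study report
#'
#' @param report A `study_report`.
#' @return A named list of scalar summaries (used for `summary.json`).
#' @export
study_summary <- function(report) {
  list(
    seed = report$settings$seed,
    n_subjects = nrow(report$records),
    n_metabolites = ncol(report$table$abundances),
    n_clamp = report$settings$n_clamp,
    n_ir = sum(report$ir_labels == "IR"),
    ir_screen_hits = sum(report$ir_screen$significant),
    median_framingham = stats::median(report$risk),
    n_high_framingham = sum(report$fram_groups == "high"),
    fram_correlates = sum(report$fram_correlates$significant),
    median_ra_supp = stats::median(report$suppression$ra_supp),
    auc_all_mean = report$ml_all$mean_auc,
    auc_all_sd = report$ml_all$sd_auc,
    auc_top_mean = report$ml_top$mean_auc,
    auc_top_sd = report$ml_top$sd_auc,
    overlap_size = length(report$overlap),
    overlap = report$overlap,
    top_features = report$ml_all$top_features,
    sanity_fraction_all = sanity_report(report$ml_all)$fraction,
    sanity_fraction_top = sanity_report(report$ml_top)$fraction,
    lipid_screen_hits = sum(report$lipolysis$lipid_screen$significant),
    all_supp_screen_hits = sum(report$lipolysis$all_screen$significant),
    clinical_correlates_q05 = report$lipolysis$clinical_correlates$parameter[
      report$lipolysis$clinical_correlates$significant
    ]
  )
}

#' Write the study report tables and summary JSON
#'
#' @param report A `study_report`.
#' @param out_dir Output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_study_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(out_dir, f)
  write_clinical_csv(report$records, p("clinical.csv"))
  utils::write.csv(report$suppression, p("suppression.csv"), row.names = FALSE)
  utils::write.csv(report$ir_screen, p("ir_screen.csv"), row.names = FALSE)
  utils::write.csv(report$fram_correlates, p("framingham_correlates.csv"),
                   row.names = FALSE)
  utils::write.csv(report$ml_all$feature_importance, p("ml_importance_all.csv"),
                   row.names = FALSE)
  utils::write.csv(report$lipolysis$clinical_correlates,
                   p("clinical_vs_suppression.csv"), row.names = FALSE)
  jsonlite::write_json(study_summary(report), p("summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
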