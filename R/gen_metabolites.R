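# Synthetic Metabolon-style two-level pathway annotation. Superpathway
# proportions put roughly half of the panel in the lipid superfamily,
# as in typical untargeted plasma panels.
.superpathways <- c(
  "Lipid" = 0.49, "Amino Acid" = 0.20, "Xenobiotics" = 0.10,
  "Peptide" = 0.05, "Carbohydrate" = 0.05, "Nucleotide" = 0.05,
  "Cofactors and Vitamins" = 0.04, "Energy" = 0.02
)

.subpathways <- list(
  "Lipid" = c(
    "Phosphatidylcholine (PC)", "Phosphatidylethanolamine (PE)",
    "Fatty Acid Metabolism (Acyl Carnitine)", "Lysophospholipid",
    "Long-Chain Polyunsaturated Fatty Acid (n3 and n6)", "Androgenic Steroids"
  ),
  "Amino Acid" = c(
    "Tyrosine Metabolism", "Leucine, Isoleucine and Valine Metabolism",
    "Methionine, Cysteine, SAM and Taurine Metabolism"
  ),
  "Xenobiotics" = c("Food Component/Plant", "Benzoate Metabolism"),
  "Peptide" = c("Dipeptide", "Gamma-glutamyl Amino Acid"),
  "Carbohydrate" = c("Glycolysis, Gluconeogenesis, and Pyruvate Metabolism"),
  "Nucleotide" = c("Purine Metabolism", "Pyrimidine Metabolism"),
  "Cofactors and Vitamins" = c("Nicotinate and Nicotinamide Metabolism"),
  "Energy" = c("TCA Cycle")
)

#' Generate a synthetic metabolite abundance table
#'
#' Abundances are log-normal per metabolite, with two kinds of planted
#' structure carried over from the simulation truth: metabolites in
#' `config$ir_effect_metabolites` are shifted by `ir_effect_size` log-SDs
#' in insulin-resistant subjects, and metabolites in
#' `config$fram_effect_metabolites` share a latent correlation of
#' `fram_effect_size` with the subject's standardized Framingham linear
#' predictor (so they correlate with the later-computed risk score).
#' Missingness is purely left-censored: only cells whose latent value
#' falls below the metabolite's detection limit (the
#' `detection_limit_quantile` of its column) can be reported missing, each
#' with probability `missing_rate`.
#'
#' @param records Clinical records from [gen_clinical()].
#' @param truth Matching truth list from [gen_clinical()].
#' @param config The [sim_config()] used to generate `records`.
#' @return A [metabolite_table()] with `NA` for censored cells. The
#'   per-metabolite detection limits are attached as attribute
#'   `detection_limits`.
#' @export
gen_metabolites <- function(records, truth, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(records)
  if (n == 0) stop("records must be nonempty")
  m <- config$n_metabolites
  if (length(config$ir_effect_metabolites) &&
      max(config$ir_effect_metabolites) > m) {
    stop("ir_effect_metabolites index out of range")
  }
  if (length(config$fram_effect_metabolites) &&
      max(config$fram_effect_metabolites) > m) {
    stop("fram_effect_metabolites index out of range")
  }

  set.seed(config$seed + 1L)
  meanlog <- stats::rnorm(m, 2, 1)
  sdlog <- stats::runif(m, 0.3, 0.8)
  z <- matrix(stats::rnorm(n * m), n, m)

  # latent Framingham driver: standardized sex-specific linear predictor
  if (length(config$fram_effect_metabolites) && config$fram_effect_size != 0) {
    lp <- framingham_linear_predictor(records)
    z_risk <- as.numeric(scale(lp))
    if (any(!is.finite(z_risk))) z_risk <- rep(0, n)
    rho <- config$fram_effect_size
    for (j in config$fram_effect_metabolites) {
      z[, j] <- rho * z_risk + sqrt(1 - rho^2) * z[, j]
    }
  }
  if (length(config$ir_effect_metabolites) && config$ir_effect_size != 0) {
    z[truth$is_ir, config$ir_effect_metabolites] <-
      z[truth$is_ir, config$ir_effect_metabolites] + config$ir_effect_size
  }
  x <- exp(sweep(sweep(z, 2, sdlog, `*`), 2, meanlog, `+`))

  sp <- sample(names(.superpathways), m, replace = TRUE, prob = .superpathways)
  sub <- vapply(sp, function(s) {
    pool <- .subpathways[[s]]
    pool[sample.int(length(pool), 1)]
  }, character(1))
  ids <- sprintf("M%04d", seq_len(m))
  annotations <- data.frame(
    metabolite_id = ids,
    biochemical_name = paste0("metabolite_", ids),
    subpathway = unname(sub),
    superpathway = sp,
    stringsAsFactors = FALSE
  )

  # left-censoring below the per-metabolite detection limit
  limits <- apply(x, 2, stats::quantile, probs = config$detection_limit_quantile,
                  names = FALSE)
  u <- matrix(stats::runif(n * m), n, m)
  censored <- sweep(x, 2, limits, `<`) & u < config$missing_rate
  x[censored] <- NA_real_

  dimnames(x) <- list(records$subject_id, ids)
  tab <- metabolite_table(x, annotations)
  attr(tab, "detection_limits") <- stats::setNames(limits, ids)
  tab
}
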