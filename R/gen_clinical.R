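# Log-normal draw parameterized by median and log-scale SD.
rlnorm_med <- function(n, median, sdlog) exp(log(median) + sdlog * stats::rnorm(n))

# Redraw until all values satisfy `ok`. Deterministic given the RNG state.
rtrunc <- function(n, draw, ok, max_tries = 1000L) {
  x <- draw(n)
  for (i in seq_len(max_tries)) {
    bad <- !ok(x)
    if (!any(bad)) return(x)
    x[bad] <- draw(sum(bad))
  }
  stop("truncated sampling failed to converge")
}

#' Generate synthetic clinical records with ground truth
#'
#' Draws per-subject demographics, anthropometry, lipids and glycemia from
#' independent scaled distributions whose medians and spreads match a
#' treatment-naive metabolic-syndrome cohort of middle-aged men (median
#' BMI ~= 33.9 kg/m2, fasting glucose ~= 5.7 mmol/L, fasting insulin
#' ~= 109 pmol/L). Insulin-resistance status (the ground truth for
#' downstream screens) is assigned at `ir_fraction`, and fasting insulin
#' and the measured glucose disposal rate `rd` are drawn conditionally on
#' it, so that `classify_ir(records$rd)` reproduces the labels.
#'
#' The returned truth also carries each subject's true percent suppression
#' of glycerol appearance under insulin, centred at
#' `clamp_true_suppression` and decreasing with log fasting insulin (more
#' hyperinsulinemic subjects suppress lipolysis less).
#'
#' @param config A [sim_config()].
#' @return A list with `records` (data frame, one row per subject) and
#'   `truth` (list: `ir_labels`, `is_ir`, `true_suppression`,
#'   `affected_metabolites`).
#' @export
gen_clinical <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_subjects
  empty <- data.frame(
    subject_id = character(), age = numeric(), sex = character(),
    bmi = numeric(), weight = numeric(), sbp = numeric(), dbp = numeric(),
    fasting_glucose = numeric(), fasting_insulin = numeric(),
    hba1c = numeric(), total_chol = numeric(), ldl = numeric(),
    hdl = numeric(), triglycerides = numeric(), smoker = logical(),
    diabetes = logical(), bp_treated = logical(), rd = numeric(),
    stringsAsFactors = FALSE
  )
  truth_affected <- list(
    ir = list(index = config$ir_effect_metabolites, effect_size = config$ir_effect_size),
    framingham = list(index = config$fram_effect_metabolites, effect_size = config$fram_effect_size)
  )
  if (n <= 0) {
    return(list(
      records = empty,
      truth = list(
        ir_labels = character(), is_ir = logical(),
        true_suppression = numeric(), affected_metabolites = truth_affected
      )
    ))
  }

  set.seed(config$seed)
  n_ir <- round(config$ir_fraction * n)
  is_ir <- sample(c(rep(TRUE, n_ir), rep(FALSE, n - n_ir)))

  age <- rtrunc(n, function(k) stats::rnorm(k, 53.8, 9.4), function(x) x > 25 & x < 80)
  bmi <- rlnorm_med(n, 33.91, 0.122)
  weight <- rlnorm_med(n, 115.4, 0.148)
  dbp <- rtrunc(n, function(k) stats::rnorm(k, 89.5, 11.1), function(x) x > 55)
  pulse <- rtrunc(n, function(k) stats::rnorm(k, 54, 12), function(x) x > 15)
  sbp <- dbp + pulse
  glucose <- rtrunc(n, function(k) stats::rnorm(k, 5.72, 0.66), function(x) x > 3.5)

  # fasting insulin conditional on IR status (pmol/L)
  insulin <- numeric(n)
  insulin[is_ir] <- rlnorm_med(sum(is_ir), 123, 0.45)
  insulin[!is_ir] <- rlnorm_med(sum(!is_ir), 69, 0.40)

  # measured glucose disposal, consistent with the IR label by construction
  rd <- numeric(n)
  rd[is_ir] <- rtrunc(sum(is_ir), function(k) rlnorm_med(k, 27, 0.38), function(x) x < 37.3)
  rd[!is_ir] <- rtrunc(sum(!is_ir), function(k) rlnorm_med(k, 48.1, 0.22), function(x) x >= 37.3)

  hba1c <- rlnorm_med(n, 39, 0.096)
  total_chol <- rlnorm_med(n, 5.0, 0.185)
  ldl <- rlnorm_med(n, 3.3, 0.31)
  hdl <- rlnorm_med(n, 1.08, 0.21)
  trig <- rlnorm_med(n, 1.40, 0.35)
  smoker <- stats::runif(n) < config$p_smoker
  diabetes <- stats::runif(n) < config$p_diabetes
  bp_treated <- stats::runif(n) < config$p_bp_treated

  z_ins <- as.numeric(scale(log(insulin)))
  if (any(!is.finite(z_ins))) z_ins <- rep(0, n)  # degenerate n = 1 case
  supp <- config$clamp_true_suppression - config$supp_insulin_slope * z_ins +
    stats::rnorm(n, 0, config$supp_sd)
  supp <- pmin(100, pmax(0, supp))

  records <- data.frame(
    subject_id = sprintf("S%04d", seq_len(n)),
    age = age, sex = config$sex, bmi = bmi, weight = weight,
    sbp = sbp, dbp = dbp, fasting_glucose = glucose,
    fasting_insulin = insulin, hba1c = hba1c, total_chol = total_chol,
    ldl = ldl, hdl = hdl, triglycerides = trig,
    smoker = smoker, diabetes = diabetes, bp_treated = bp_treated,
    rd = rd, stringsAsFactors = FALSE
  )
  truth <- list(
    ir_labels = ifelse(is_ir, "IR", "N-IR"),
    is_ir = is_ir,
    true_suppression = supp,
    affected_metabolites = truth_affected
  )
  list(records = records, truth = truth)
}
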