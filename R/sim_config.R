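#' Simulation configuration for synthetic metabolic-syndrome cohorts
#'
#' Defines the study conditions the generators emulate: a cohort of
#' treatment-naive men with metabolic syndrome (132 subjects by default),
#' an untargeted metabolomics panel of 917 annotated metabolites with
#' log-normal abundances and left-censored missingness, planted group
#' effects on designated metabolite subsets, and one-pool glycerol clamp
#' kinetics with insulin-suppressed appearance.
#'
#' @param n_subjects Cohort size. Default 132.
#' @param n_metabolites Number of annotated metabolites. Default 917.
#' @param seed Integer seed; the same config yields bit-identical cohorts.
#' @param ir_fraction Fraction of subjects that are peripherally insulin
#'   resistant (Rd < 37.3 umol/kg/min). Default 92/132.
#' @param ir_effect_metabolites Indices of metabolites carrying a planted
#'   abundance shift in IR subjects. Default `1:14`.
#' @param ir_effect_size Standardized log-scale mean shift for the IR
#'   effect, in units of each metabolite's log-SD. Default 1.
#' @param fram_effect_metabolites Indices of metabolites correlated with
#'   the subject's Framingham risk driver. Must be disjoint from
#'   `ir_effect_metabolites`. Default `15:47` (33 metabolites).
#' @param fram_effect_size Latent correlation strength in \[-1, 1\] between
#'   the planted metabolites' log abundance and the standardized
#'   Framingham linear predictor. Default 0.4.
#' @param missing_rate Probability that a cell below its metabolite's
#'   detection limit is reported missing. Default 0.5.
#' @param detection_limit_quantile Column quantile defining the detection
#'   limit. Default 0.1.
#' @param clamp_true_suppression Cohort-centre true percent suppression of
#'   glycerol appearance under insulin. Default 68.1.
#' @param clamp_noise_cv Coefficient of variation of multiplicative
#'   measurement noise on clamp concentration and enrichment. Default 0.05.
#' @param supp_insulin_slope Percentage-point decrease in true suppression
#'   per SD of log fasting insulin (plants the insulin/HOMA-IR vs
#'   suppression association). Default 8.
#' @param supp_sd Between-subject SD (percentage points) of true
#'   suppression around its insulin-driven mean. Default 6.
#' @param p_smoker,p_diabetes,p_bp_treated Bernoulli rates for the smoking,
#'   diabetes, and blood-pressure-treatment flags. The cohort is
#'   treatment-naive, so diabetes and BP treatment default to 0.
#' @param sex Sex assigned to all generated subjects. Default "male".
#' @param clamp List of clamp-protocol parameters: `ra_basal_median` and
#'   `ra_basal_sdlog` (basal glycerol appearance, umol/kg/min, log-normal
#'   across subjects), `c_basal_median` and `c_basal_sdlog` (basal plasma
#'   glycerol, umol/L), `volume` (distribution volume, L/kg), `f_inf`
#'   (tracer infusion rate, umol/kg/min), `t_half` (half-time of the
#'   insulin-induced mono-exponential Ra decline, min), `tracer_start`
#'   (min, tracer infusion onset relative to insulin start at t = 0),
#'   `insulin_end` (min), and `times` (sampling schedule, min).
#'
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_subjects = 132,
                       n_metabolites = 917,
                       seed = 1,
                       ir_fraction = 92 / 132,
                       ir_effect_metabolites = 1:14,
                       ir_effect_size = 1,
                       fram_effect_metabolites = 15:47,
                       fram_effect_size = 0.4,
                       missing_rate = 0.5,
                       detection_limit_quantile = 0.1,
                       clamp_true_suppression = 68.1,
                       clamp_noise_cv = 0.05,
                       supp_insulin_slope = 8,
                       supp_sd = 6,
                       p_smoker = 0.25,
                       p_diabetes = 0,
                       p_bp_treated = 0,
                       sex = "male",
                       clamp = list()) {
  clamp_defaults <- list(
    ra_basal_median = 2.5, ra_basal_sdlog = 0.25,
    c_basal_median = 80, c_basal_sdlog = 0.15,
    volume = 0.23, f_inf = 0.1, t_half = 30,
    tracer_start = -120, insulin_end = 240,
    times = c(-30, -15, 0, 30, 60, 90, 120, 150, 180, 210, 225, 240)
  )
  unknown <- setdiff(names(clamp), names(clamp_defaults))
  if (length(unknown)) stop("unknown clamp parameter(s): ", paste(unknown, collapse = ", "))
  clamp <- utils::modifyList(clamp_defaults, clamp)

  cfg <- list(
    n_subjects = as.integer(n_subjects),
    n_metabolites = as.integer(n_metabolites),
    seed = as.integer(seed),
    ir_fraction = ir_fraction,
    ir_effect_metabolites = as.integer(ir_effect_metabolites),
    ir_effect_size = ir_effect_size,
    fram_effect_metabolites = as.integer(fram_effect_metabolites),
    fram_effect_size = fram_effect_size,
    missing_rate = missing_rate,
    detection_limit_quantile = detection_limit_quantile,
    clamp_true_suppression = clamp_true_suppression,
    clamp_noise_cv = clamp_noise_cv,
    supp_insulin_slope = supp_insulin_slope,
    supp_sd = supp_sd,
    p_smoker = p_smoker,
    p_diabetes = p_diabetes,
    p_bp_treated = p_bp_treated,
    sex = match.arg(sex, c("male", "female")),
    clamp = clamp
  )

  frac <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) && x >= 0 && x <= 1
  if (!frac(cfg$ir_fraction)) stop("ir_fraction must be a fraction in [0, 1]")
  if (!frac(cfg$missing_rate)) stop("missing_rate must be a fraction in [0, 1]")
  if (!frac(cfg$detection_limit_quantile)) {
    stop("detection_limit_quantile must be a fraction in [0, 1]")
  }
  if (!is.numeric(cfg$fram_effect_size) || abs(cfg$fram_effect_size) > 1) {
    stop("fram_effect_size must lie in [-1, 1]")
  }
  if (cfg$clamp_true_suppression < 0 || cfg$clamp_true_suppression > 100) {
    stop("clamp_true_suppression must lie in [0, 100]")
  }
  if (cfg$clamp_noise_cv < 0) stop("clamp_noise_cv must be >= 0")
  idx <- c(cfg$ir_effect_metabolites, cfg$fram_effect_metabolites)
  if (length(idx) && (any(idx < 1) || any(idx > cfg$n_metabolites))) {
    stop("effect metabolite indices must lie in [1, n_metabolites]")
  }
  if (length(intersect(cfg$ir_effect_metabolites, cfg$fram_effect_metabolites))) {
    stop("ir_effect_metabolites and fram_effect_metabolites must be disjoint")
  }
  with(cfg$clamp, {
    if (volume <= 0 || f_inf <= 0 || t_half <= 0) {
      stop("clamp volume, f_inf and t_half must be positive")
    }
    if (tracer_start >= 0) stop("clamp tracer_start must precede insulin start (t = 0)")
    if (any(diff(times) <= 0)) stop("clamp times must be strictly increasing")
  })
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    paste0(
      "sim_config: %d subjects, %d metabolites (seed %d)\n",
      "  IR fraction %.2f; planted IR effects: %d metabolites at %.2f log-SD\n",
      "  Framingham correlates: %d metabolites at rho = %.2f\n",
      "  missingness: rate %.2f below the %.0f%% column quantile\n",
      "  clamp: true suppression %.1f%%, noise CV %.2f\n"
    ),
    x$n_subjects, x$n_metabolites, x$seed, x$ir_fraction,
    length(x$ir_effect_metabolites), x$ir_effect_size,
    length(x$fram_effect_metabolites), x$fram_effect_size,
    x$missing_rate, 100 * x$detection_limit_quantile,
    x$clamp_true_suppression, x$clamp_noise_cv
  ))
  invisible(x)
}
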