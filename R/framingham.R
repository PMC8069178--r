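#' Framingham general-CVD risk coefficients
#'
#' Loads the sex-specific Cox-model coefficients of the 2008 Framingham
#' general cardiovascular disease risk function (lipid-based variant)
#' from a versioned JSON file shipped with the package. The continuous
#' covariates enter on the log scale; lipid coefficients are defined on
#' mg/dL.
#'
#' @param path Path to a coefficients JSON; defaults to the shipped file.
#' @return A list of class `framingham_coefficients` with elements
#'   `male`, `female` (each: `ln_age`, `ln_total_chol`, `ln_hdl`,
#'   `ln_sbp_untreated`, `ln_sbp_treated`, `smoker`, `diabetes`,
#'   `mean_lp`, `s0_10yr`).
#' @export
framingham_coefficients <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "framingham_general_cvd_2008.json",
                        package = "metsynflux", mustWork = TRUE)
  }
  coefs <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (sex in c("male", "female")) {
    cs <- coefs[[sex]]
    need <- c("ln_age", "ln_total_chol", "ln_hdl", "ln_sbp_untreated",
              "ln_sbp_treated", "smoker", "diabetes", "mean_lp", "s0_10yr")
    if (is.null(cs) || !all(need %in% names(cs))) {
      stop("incomplete coefficient set for sex: ", sex)
    }
    if (cs$s0_10yr <= 0 || cs$s0_10yr >= 1) stop("baseline survival must lie in (0, 1)")
  }
  structure(coefs, class = "framingham_coefficients")
}

# mmol/L -> mg/dL for cholesterol
.chol_mgdl <- 38.67

# Sex-specific linear predictor on log-transformed continuous covariates.
framingham_linear_predictor <- function(records,
                                        coefs = framingham_coefficients(),
                                        lipid_unit = c("mmol/L", "mg/dL")) {
  lipid_unit <- match.arg(lipid_unit)
  need <- c("age", "sex", "total_chol", "hdl", "sbp", "bp_treated",
            "smoker", "diabetes")
  absent <- setdiff(need, names(records))
  if (length(absent)) {
    stop("missing Framingham covariate(s): ", paste(absent, collapse = ", "))
  }
  has_na <- need[vapply(need, function(v) any(is.na(records[[v]])), logical(1))]
  if (length(has_na)) {
    stop("Framingham covariate(s) with missing values: ",
         paste(has_na, collapse = ", "))
  }
  if (!all(records$sex %in% c("male", "female"))) {
    stop("sex must be \"male\" or \"female\"")
  }
  tc <- records$total_chol
  hdl <- records$hdl
  if (lipid_unit == "mmol/L") {
    tc <- tc * .chol_mgdl
    hdl <- hdl * .chol_mgdl
  }
  if (any(records$age <= 0) || any(tc <= 0) || any(hdl <= 0) || any(records$sbp <= 0)) {
    stop("log-transformed covariates must be positive")
  }
  lp <- numeric(nrow(records))
  for (sex in c("male", "female")) {
    sel <- records$sex == sex
    if (!any(sel)) next
    cs <- coefs[[sex]]
    b_sbp <- ifelse(records$bp_treated[sel], cs$ln_sbp_treated, cs$ln_sbp_untreated)
    lp[sel] <- cs$ln_age * log(records$age[sel]) +
      cs$ln_total_chol * log(tc[sel]) +
      cs$ln_hdl * log(hdl[sel]) +
      b_sbp * log(records$sbp[sel]) +
      cs$smoker * as.numeric(records$smoker[sel]) +
      cs$diabetes * as.numeric(records$diabetes[sel])
  }
  lp
}

#' 10-year Framingham general cardiovascular risk
#'
#' Computes the sex-specific 10-year risk (percent) of a general
#' cardiovascular event from age, total cholesterol, HDL cholesterol,
#' systolic blood pressure (with separate coefficients when treated),
#' smoking and diabetes status:
#' risk = 100 (1 - S0^exp(LP - meanLP)), with LP the linear predictor on
#' log-transformed continuous covariates and S0 the sex-specific 10-year
#' baseline survival.
#'
#' @param records Data frame with columns `age` (years), `sex`
#'   ("male"/"female"), `total_chol`, `hdl` (in `lipid_unit`), `sbp`
#'   (mmHg), `bp_treated`, `smoker`, `diabetes` (logical). A missing or
#'   NA covariate raises an error naming it.
#' @param coefs A [framingham_coefficients()].
#' @param lipid_unit Unit of the cholesterol columns; "mmol/L" (default,
#'   converted internally) or "mg/dL".
#' @return Numeric vector of risks in percent, in (0, 100).
#' @export
framingham_risk <- function(records, coefs = framingham_coefficients(),
                            lipid_unit = c("mmol/L", "mg/dL")) {
  lipid_unit <- match.arg(lipid_unit)
  lp <- framingham_linear_predictor(records, coefs, lipid_unit)
  risk <- numeric(length(lp))
  for (sex in c("male", "female")) {
    sel <- records$sex == sex
    if (!any(sel)) next
    cs <- coefs[[sex]]
    risk[sel] <- 100 * (1 - cs$s0_10yr^exp(lp[sel] - cs$mean_lp))
  }
  risk
}

#' Dichotomize Framingham risk at a cutoff
#'
#' Splits a cohort into high and low CVD-risk groups; a risk at or above
#' the cutoff (default 12%, just below a typical metabolic-syndrome
#' cohort median) is "high".
#'
#' @param risk_percent Risk in percent. Vectorized.
#' @param cutoff Threshold in percent, default 12.
#' @return Character vector of "high" / "low".
#' @export
dichotomize_framingham <- function(risk_percent, cutoff = 12) {
  if (any(!is.finite(risk_percent))) stop("risk must be finite")
  ifelse(risk_percent >= cutoff, "high", "low")
}
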