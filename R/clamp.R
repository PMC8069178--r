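#' Construct a clamp tracer time series
#'
#' A per-subject tracer time course from a primed/continuous isotope
#' infusion during a hyperinsulinemic euglycemic clamp: sampling times
#' (minutes, insulin infusion starts at t = 0), phase labels, tracer
#' infusion rate `f_inf` (umol/kg/min), total plasma tracee concentration
#' `conc` (umol/L), and plasma enrichment `enrich` (tracer mole fraction
#' of total concentration, dimensionless in (0, 1)). `gir` carries the
#' exogenous glucose infusion rate for glucose tracer series (0 for
#' glycerol).
#'
#' @param subject_id Subject identifier.
#' @param time Strictly increasing sampling times (min).
#' @param phase Per-point label in `basal`, `step1`, `step2`.
#' @param f_inf Tracer infusion rate per point (umol/kg/min, >= 0).
#' @param conc Plasma concentration per point (umol/L, > 0).
#' @param enrich Enrichment per point (fraction in (0, 1)).
#' @param gir Exogenous glucose infusion rate (umol/kg/min), default 0.
#' @return A data frame of class `clamp_series`.
#' @export
clamp_series <- function(subject_id, time, phase, f_inf, conc, enrich, gir = 0) {
  n <- length(time)
  phase <- as.character(phase)
  f_inf <- rep_len(f_inf, n)
  gir <- rep_len(gir, n)
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  if (!all(phase %in% c("basal", "step1", "step2"))) {
    stop("phase labels must be basal, step1 or step2")
  }
  if (any(conc <= 0)) stop("concentration must be positive")
  if (any(enrich <= 0 | enrich >= 1)) stop("enrichment must lie strictly in (0, 1)")
  if (any(f_inf < 0)) stop("tracer infusion rate must be >= 0")
  structure(
    data.frame(
      subject_id = subject_id, time = time, phase = phase,
      f_inf = f_inf, conc = conc, enrich = enrich, gir = gir,
      stringsAsFactors = FALSE
    ),
    class = c("clamp_series", "data.frame")
  )
}

# Closed-form one-pool kinetics. Single well-mixed pool of distribution
# volume `volume` (L/kg): endogenous appearance ra(t) and tracer infusion
# f_inf enter, disposal is first-order in pool content with rate constant
# k fixed by basal equilibrium, and removal is non-discriminating, so the
# tracer leaves in proportion to its mole fraction. ra(t) is constant at
# ra_basal until insulin start (t = 0), then declines mono-exponentially
# with half-time t_half towards (1 - supp_pct/100) * ra_basal.
one_pool_profile <- function(times, f_inf, volume, c_basal, ra_basal,
                             supp_pct, t_half, tracer_start = -120) {
  if (any(times < tracer_start)) stop("sampling before tracer infusion start")
  k <- (ra_basal + f_inf) / (volume * c_basal)
  lambda <- log(2) / t_half
  if (abs(k - lambda) < 1e-10) lambda <- lambda * (1 + 1e-8)  # avoid resonance
  ra_inf <- (1 - supp_pct / 100) * ra_basal
  d_ra <- ra_basal - ra_inf

  q_ee0 <- ra_basal / k                 # endogenous pool, equilibrated pre-insulin
  q_tr <- function(t) {
    q0 <- (f_inf / k) * (1 - exp(-k * (0 - tracer_start)))
    ifelse(t <= 0,
      (f_inf / k) * (1 - exp(-k * (t - tracer_start))),
      f_inf / k + (q0 - f_inf / k) * exp(-k * t)
    )
  }
  q_ee <- function(t) {
    ifelse(t <= 0, q_ee0,
      ra_inf / k + d_ra / (k - lambda) * exp(-lambda * t) +
        (q_ee0 - ra_inf / k - d_ra / (k - lambda)) * exp(-k * t)
    )
  }
  ra_t <- function(t) ifelse(t <= 0, ra_basal, ra_inf + d_ra * exp(-lambda * t))

  qe <- q_ee(times)
  qt <- q_tr(times)
  list(
    time = times,
    conc = (qe + qt) / volume,
    enrich = qt / (qe + qt),
    ra_true = ra_t(times),
    params = list(
      k = k, lambda = lambda, volume = volume, f_inf = f_inf,
      ra_basal = ra_basal, ra_inf = ra_inf, supp_pct = supp_pct,
      tracer_start = tracer_start
    ),
    q_ee = q_ee, q_tr = q_tr, ra_fun = ra_t
  )
}

#' True time-averaged endogenous appearance of a simulated series
#'
#' Closed-form mean of the simulated Ra(t) over a window; the oracle
#' against which windowed non-steady-state estimates are compared.
#'
#' @param series A `clamp_series` produced by [gen_clamp()].
#' @param t_start,t_end Window bounds (min), both >= 0.
#' @return Mean Ra over the window (umol/kg/min).
#' @export
true_ra_mean <- function(series, t_start, t_end) {
  p <- attr(series, "true_params")
  if (is.null(p)) stop("series carries no simulation truth")
  if (t_start < 0 || t_end <= t_start) stop("window must be ordered and >= 0")
  d_ra <- p$ra_basal - p$ra_inf
  p$ra_inf + d_ra * (exp(-p$lambda * t_start) - exp(-p$lambda * t_end)) /
    (p$lambda * (t_end - t_start))
}

#' Forward-simulate clamp tracer series for a cohort
#'
#' For each subject a one-pool glycerol tracer model is simulated: basal
#' endogenous appearance (log-normal across subjects), constant tracer
#' infusion from `tracer_start`, and a mono-exponential decline of
#' appearance after insulin start to the subject's true suppression
#' plateau from `truth$true_suppression`. Concentration and enrichment are
#' sampled at `config$clamp$times` with multiplicative log-normal noise of
#' coefficient of variation `config$clamp_noise_cv`.
#'
#' The default protocol labels all post-insulin samples `step1`; a second
#' insulin step is not simulated (its infusion rate is not a published
#' quantity and step2 data are unused downstream).
#'
#' @param records Clinical records (one row per subject to simulate).
#' @param truth Truth list aligned with `records` (per-subject
#'   `true_suppression`).
#' @param config A [sim_config()].
#' @return Named list of `clamp_series`, one per subject, each carrying
#'   its true kinetic parameters in attribute `true_params`.
#' @export
gen_clamp <- function(records, truth, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  n <- nrow(records)
  if (n == 0) stop("records must be nonempty")
  supp <- truth$true_suppression
  if (length(supp) != n) stop("truth$true_suppression must match records")
  if (any(supp < 0 | supp > 100)) stop("true suppression must lie in [0, 100]")

  cl <- config$clamp
  set.seed(config$seed + 2L)
  ra_basal <- rlnorm_med(n, cl$ra_basal_median, cl$ra_basal_sdlog)
  c_basal <- rlnorm_med(n, cl$c_basal_median, cl$c_basal_sdlog)
  sdl <- sqrt(log(1 + config$clamp_noise_cv^2))
  noise <- function(k) exp(sdl * stats::rnorm(k) - sdl^2 / 2)

  phases <- ifelse(cl$times <= 0, "basal",
                   ifelse(cl$times <= cl$insulin_end, "step1", "step2"))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    prof <- one_pool_profile(
      cl$times, cl$f_inf, cl$volume, c_basal[i], ra_basal[i],
      supp[i], cl$t_half, cl$tracer_start
    )
    conc <- prof$conc * noise(length(cl$times))
    enrich <- pmin(1 - 1e-9, prof$enrich * noise(length(cl$times)))
    s <- clamp_series(records$subject_id[i], cl$times, phases,
                      cl$f_inf, conc, enrich)
    attr(s, "true_params") <- prof$params
    out[[i]] <- s
  }
  names(out) <- records$subject_id
  out
}
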