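#' Steele model constants
#'
#' Pool fraction and distribution volume for the single-pool (Steele)
#' isotope-dilution model. Defaults follow the conventional values for
#' primed-continuous tracer clamps: pool fraction 0.65 and distribution
#' volume 0.22 L/kg for glucose; glycerol series conventionally use
#' 0.23 L/kg.
#'
#' @param p Pool fraction, in (0, 1].
#' @param volume Distribution volume, L/kg, > 0.
#' @return A list of class `steele_params`.
#' @export
steele_params <- function(p = 0.65, volume = 0.22) {
  if (!is.numeric(p) || p <= 0 || p > 1) stop("pool fraction p must lie in (0, 1]")
  if (!is.numeric(volume) || volume <= 0) stop("distribution volume must be > 0")
  structure(list(p = p, volume = volume), class = "steele_params")
}

#' Steady-state Steele rate of appearance
#'
#' At isotopic steady state the endogenous rate of appearance follows
#' from tracer dilution: Ra = F/E - F, where F is the tracer infusion
#' rate and E the plasma enrichment (tracer fraction). The subtraction
#' removes the tracer's own contribution to turnover; set
#' `correct_tracer = FALSE` for the uncorrected F/E.
#'
#' @param f_inf Tracer infusion rate (umol/kg/min), > 0. Vectorized.
#' @param enrich Enrichment, fraction strictly in (0, 1). Vectorized.
#' @param correct_tracer Subtract the tracer infusion (default `TRUE`).
#' @return Ra (umol/kg/min).
#' @export
steele_steady <- function(f_inf, enrich, correct_tracer = TRUE) {
  if (any(!is.finite(f_inf)) || any(f_inf <= 0)) stop("f_inf must be positive")
  if (any(!is.finite(enrich)) || any(enrich <= 0 | enrich >= 1)) {
    stop("enrichment must lie strictly in (0, 1)")
  }
  f_inf / enrich - if (correct_tracer) f_inf else 0
}

#' Non-steady-state (modified Steele) flux estimates
#'
#' For each consecutive pair of samples (t1, t2) the endogenous rate of
#' appearance is estimated as
#' Ra = (Fbar - p V Cbar (E2 - E1)/(t2 - t1)) / Ebar - Fbar
#' and the rate of disappearance as Rd = Ra - p V (C2 - C1)/(t2 - t1),
#' with Cbar, Ebar, Fbar the pairwise means, p the pool fraction and V
#' the distribution volume. In the steady limit (constant C and E) this
#' reduces exactly to [steele_steady()]. For glucose series with an
#' exogenous glucose infusion, endogenous production is Ra minus the mean
#' infusion rate and is reported as `egp`.
#'
#' Negative estimates (possible with noisy non-steady data) are returned
#' as-is and flagged with a warning rather than clipped.
#'
#' @param series A [clamp_series()] (or data frame with its columns).
#' @param params A [steele_params()].
#' @param correct_tracer Subtract the tracer infusion (default `TRUE`).
#' @return Data frame with one row per consecutive pair: `t_start`,
#'   `t_end`, `t_mid`, `phase` (of the pair's end point), `ra`, `rd`,
#'   `egp`, `negative` flag.
#' @export
steele_nonsteady <- function(series, params = steele_params(), correct_tracer = TRUE) {
  if (nrow(series) < 2) stop("need at least 2 points per evaluated window")
  t <- series$time
  if (any(diff(t) <= 0)) stop("time must be strictly increasing")
  i1 <- seq_len(nrow(series) - 1)
  i2 <- i1 + 1
  dt <- t[i2] - t[i1]
  cbar <- (series$conc[i1] + series$conc[i2]) / 2
  ebar <- (series$enrich[i1] + series$enrich[i2]) / 2
  fbar <- (series$f_inf[i1] + series$f_inf[i2]) / 2
  if (any(ebar <= 0)) stop("mean enrichment must be positive")
  dedt <- (series$enrich[i2] - series$enrich[i1]) / dt
  dcdt <- (series$conc[i2] - series$conc[i1]) / dt
  pv <- params$p * params$volume
  ra <- (fbar - pv * cbar * dedt) / ebar - if (correct_tracer) fbar else 0
  rd <- ra - pv * dcdt
  gbar <- (series$gir[i1] + series$gir[i2]) / 2
  out <- data.frame(
    t_start = t[i1], t_end = t[i2], t_mid = (t[i1] + t[i2]) / 2,
    phase = series$phase[i2], ra = ra, rd = rd, egp = ra - gbar,
    negative = ra < 0 | rd < 0, stringsAsFactors = FALSE
  )
  if (any(out$negative)) {
    warning("negative flux estimate(s); check data quality (not clipped)")
  }
  out
}

#' Percent suppression of tracee appearance under insulin
#'
#' Basal Ra is the steady-state Steele estimate from the mean basal-phase
#' infusion rate and enrichment (t <= 0). Clamp Ra is the mean of
#' non-steady-state estimates over the final `clamp_window` minutes of
#' the first insulin step, where the appearance rate has plateaued.
#' Suppression is 100 (Ra_basal - Ra_clamp) / Ra_basal.
#'
#' @param series A [clamp_series()] containing basal and step1 points.
#' @param params A [steele_params()]; the default uses the glycerol
#'   distribution volume 0.23 L/kg.
#' @param clamp_window Width (min) of the terminal step1 window. Default 30.
#' @return List of class `suppression_result`: `ra_basal`, `ra_clamp`,
#'   `ra_supp` (percent).
#' @export
estimate_suppression <- function(series, params = steele_params(volume = 0.23),
                                 clamp_window = 30) {
  basal <- series[series$phase == "basal", , drop = FALSE]
  step1 <- series[series$phase == "step1", , drop = FALSE]
  if (nrow(basal) == 0) stop("series has no basal-phase points")
  if (nrow(step1) < 2) stop("series needs at least 2 step1-phase points")
  ra_basal <- steele_steady(mean(basal$f_inf), mean(basal$enrich))
  if (ra_basal <= 0) stop("non-positive basal Ra; cannot compute suppression")
  t_end <- max(step1$time)
  win <- step1[step1$time >= t_end - clamp_window, , drop = FALSE]
  if (nrow(win) < 2) stop("fewer than 2 step1 points in the terminal window")
  flux <- withCallingHandlers(
    steele_nonsteady(win, params),
    warning = function(w) invokeRestart("muffleWarning")
  )
  ra_clamp <- mean(flux$ra)
  structure(
    list(
      ra_basal = ra_basal, ra_clamp = ra_clamp,
      ra_supp = 100 * (ra_basal - ra_clamp) / ra_basal,
      window = c(t_end - clamp_window, t_end)
    ),
    class = "suppression_result"
  )
}

#' @export
print.suppression_result <- function(x, ...) {
  cat(sprintf(
    "Ra basal %.3f, Ra clamp %.3f umol/kg/min -> suppression %.1f%% (window %g-%g min)\n",
    x$ra_basal, x$ra_clamp, x$ra_supp, x$window[1], x$window[2]
  ))
  invisible(x)
}

#' Classify peripheral insulin resistance from the glucose disposal rate
#'
#' Subjects with an insulin-stimulated rate of glucose disposal (Rd)
#' below 37.3 umol/kg/min are classified insulin resistant ("IR");
#' Rd >= 37.3 is non-insulin-resistant ("N-IR").
#'
#' @param rd Rd in umol/kg/min. Vectorized.
#' @param cutoff Classification threshold, default 37.3.
#' @return Character vector of "IR" / "N-IR".
#' @export
classify_ir <- function(rd, cutoff = 37.3) {
  if (any(!is.finite(rd))) stop("rd must be finite")
  ifelse(rd < cutoff, "IR", "N-IR")
}
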