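#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two samples. Small untied samples use
#' the exact U distribution; larger samples or ties use the tie-corrected
#' normal approximation with continuity correction (the default behaviour
#' of [stats::wilcox.test()]).
#'
#' @param x,y Numeric samples, both nonempty.
#' @return List with `statistic` (U, the number of (x, y) pairs with
#'   x > y, ties counted half) and `p_value`.
#' @export
mann_whitney_u <- function(x, y) {
  x <- x[!is.na(x)]
  y <- y[!is.na(y)]
  if (length(x) == 0 || length(y) == 0) stop("both samples must be nonempty")
  ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided"))
  list(statistic = unname(ht$statistic), p_value = ht$p.value)
}

#' Spearman rank correlation
#'
#' Rank correlation with average ranks for ties and a two-sided p-value.
#' A constant input vector leaves the correlation undefined; this is
#' flagged rather than raised.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho`, `p_value`, and `undefined` (TRUE when either
#'   vector is constant, in which case `rho` and `p_value` are NA).
#' @export
spearman_rho <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]
  y <- y[keep]
  if (length(x) != length(y)) stop("x and y must have equal length")
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(rho = NA_real_, p_value = NA_real_, undefined = TRUE))
  }
  ht <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ht$estimate), p_value = ht$p.value, undefined = FALSE)
}

#' False-discovery-rate adjusted q-values
#'
#' Benjamini-Hochberg step-up q-values (default), or the
#' Benjamini-Yekutieli variant for arbitrary dependence.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\]; NA allowed and
#'   propagated.
#' @param method "BH" (default) or "BY".
#' @return q-values in input order.
#' @export
bh_fdr <- function(p_values, method = c("BH", "BY")) {
  method <- match.arg(method)
  ok <- !is.na(p_values)
  if (any(p_values[ok] < 0 | p_values[ok] > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = method)
}

#' HOMA-IR
#'
#' Homeostatic model assessment of insulin resistance from fasting
#' glucose (mmol/L) and fasting insulin (pmol/L):
#' HOMA-IR = glucose x insulin\[uU/mL\] / 22.5 with
#' insulin\[uU/mL\] = insulin\[pmol/L\] / 6.945.
#'
#' @param glucose Fasting glucose, mmol/L, > 0. Vectorized.
#' @param insulin Fasting insulin, pmol/L, > 0. Vectorized.
#' @return HOMA-IR values.
#' @export
homa_ir <- function(glucose, insulin) {
  if (any(!is.finite(glucose)) || any(glucose <= 0)) stop("glucose must be positive")
  if (any(!is.finite(insulin)) || any(insulin <= 0)) stop("insulin must be positive")
  glucose * (insulin / 6.945) / 22.5
}

.screen_annotations <- function(table) {
  ann <- table$annotations
  data.frame(
    metabolite_id = ann$metabolite_id,
    subpathway = ann$subpathway,
    superpathway = ann$superpathway,
    stringsAsFactors = FALSE
  )
}

#' Group comparison screen over all metabolites
#'
#' Mann-Whitney U test per metabolite between two groups, with
#' Benjamini-Hochberg FDR control across the supplied metabolite family.
#' The multiplicity family is whatever table is passed in, so a screen
#' can be restricted to, e.g., the lipid superpathway by subsetting
#' first.
#'
#' @param table A preprocessed (no missing values) [metabolite_table()].
#' @param labels Group label per sample; exactly two distinct values.
#' @param alpha_q Significance threshold on q-values. Default 0.05.
#' @return Data frame, one row per metabolite: `metabolite_id`,
#'   `subpathway`, `superpathway`, `statistic` (U), `p_value`, `q_value`,
#'   `direction` (sign of median difference, first group minus second),
#'   `n_used`, `significant`.
#' @export
screen_groups <- function(table, labels, alpha_q = 0.05) {
  stopifnot(inherits(table, "metabolite_table"))
  ab <- table$abundances
  if (any(is.na(ab))) stop("table contains missing values; impute first")
  if (length(labels) != nrow(ab)) stop("labels must cover all samples")
  labels <- as.character(labels)
  lev <- unique(labels)
  if (length(lev) != 2) stop("labels must contain exactly two classes")
  g1 <- labels == lev[1]
  res <- apply(ab, 2, function(col) {
    ht <- mann_whitney_u(col[g1], col[!g1])
    c(ht$statistic, ht$p_value,
      sign(stats::median(col[g1]) - stats::median(col[!g1])))
  })
  out <- .screen_annotations(table)
  out$statistic <- res[1, ]
  out$p_value <- res[2, ]
  out$q_value <- bh_fdr(out$p_value)
  out$direction <- res[3, ]
  out$n_used <- nrow(ab)
  out$significant <- !is.na(out$q_value) & out$q_value < alpha_q
  attr(out, "groups") <- lev
  out
}

#' Rank-correlation screen over all metabolites
#'
#' Spearman correlation of each metabolite with a continuous outcome,
#' with Benjamini-Hochberg FDR control across the supplied family.
#' Metabolites with undefined correlation (constant abundance) get NA
#' statistics and are never flagged significant.
#'
#' @param table A preprocessed [metabolite_table()].
#' @param outcome Numeric outcome per sample (NA allowed; pairs with NA
#'   outcome are dropped per metabolite).
#' @param alpha_q Significance threshold on q-values. Default 0.05.
#' @return Data frame as in [screen_groups()], with `statistic` = rho and
#'   `direction` = sign(rho).
#' @export
screen_correlation <- function(table, outcome, alpha_q = 0.05) {
  stopifnot(inherits(table, "metabolite_table"))
  ab <- table$abundances
  if (any(is.na(ab))) stop("table contains missing values; impute first")
  if (length(outcome) != nrow(ab)) stop("outcome must cover all samples")
  res <- apply(ab, 2, function(col) {
    ht <- spearman_rho(col, outcome)
    c(ht$rho, ht$p_value, sum(!is.na(col) & !is.na(outcome)))
  })
  out <- .screen_annotations(table)
  out$statistic <- res[1, ]
  out$p_value <- res[2, ]
  out$q_value <- bh_fdr(out$p_value)
  out$direction <- sign(out$statistic)
  out$n_used <- res[3, ]
  out$significant <- !is.na(out$q_value) & out$q_value < alpha_q
  out
}
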