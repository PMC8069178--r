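#' Rescale every metabolite to unit median
#'
#' Divides each metabolite's non-missing abundances by their median, so
#' that after rescaling every metabolite's non-missing median equals 1.
#' Missing cells remain missing. This is the standard block-level
#' normalization applied to untargeted panel data before imputation.
#'
#' @param table A [metabolite_table()].
#' @return The rescaled `metabolite_table`.
#' @export
median_rescale <- function(table) {
  stopifnot(inherits(table, "metabolite_table"))
  ab <- table$abundances
  meds <- apply(ab, 2, stats::median, na.rm = TRUE)
  bad <- !is.finite(meds)
  if (any(bad)) {
    stop("metabolite(s) with no non-missing values: ",
         paste(colnames(ab)[bad], collapse = ", "))
  }
  zero <- meds == 0
  if (any(zero)) {
    stop("metabolite(s) with zero median cannot be rescaled: ",
         paste(colnames(ab)[zero], collapse = ", "))
  }
  out <- metabolite_table(sweep(ab, 2, meds, `/`), table$annotations)
  attr(out, "detection_limits") <- attr(table, "detection_limits")
  out
}

#' Impute missing abundances at half the observed minimum
#'
#' Replaces each missing cell by 50% of the minimum non-missing value of
#' the same metabolite across all samples, the conventional surrogate for
#' measurements below the detection limit. After imputation no missing
#' cells remain, and every imputed value sits at the bottom of its
#' metabolite's distribution.
#'
#' @param table A [metabolite_table()].
#' @return The imputed `metabolite_table`.
#' @export
impute_half_min <- function(table) {
  stopifnot(inherits(table, "metabolite_table"))
  ab <- table$abundances
  mins <- suppressWarnings(apply(ab, 2, min, na.rm = TRUE))
  bad <- !is.finite(mins)
  if (any(bad)) {
    stop("metabolite(s) with no non-missing values: ",
         paste(colnames(ab)[bad], collapse = ", "))
  }
  idx <- which(is.na(ab), arr.ind = TRUE)
  if (nrow(idx)) ab[idx] <- 0.5 * mins[idx[, "col"]]
  out <- metabolite_table(ab, table$annotations)
  attr(out, "detection_limits") <- attr(table, "detection_limits")
  out
}

#' Standard preprocessing pipeline
#'
#' Median rescaling followed by half-minimum imputation, in that fixed
#' order (normalize first, then impute; the imputed value is then half the
#' minimum of the rescaled column).
#'
#' @param table A [metabolite_table()].
#' @param impute Set `FALSE` to rescale only.
#' @return The preprocessed `metabolite_table`.
#' @export
preprocess_table <- function(table, impute = TRUE) {
  out <- median_rescale(table)
  if (impute) out <- impute_half_min(out)
  out
}
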