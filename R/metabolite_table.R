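#' Construct a metabolite abundance table
#'
#' Bundles a samples x metabolites abundance matrix with per-metabolite
#' pathway annotations. Missing measurements (typically values below the
#' assay detection limit) are encoded as `NA`.
#'
#' @param abundances Numeric matrix, samples in rows, metabolites in
#'   columns. Non-negative; `NA` marks missing cells. Row names are sample
#'   ids, column names metabolite ids (generated when absent).
#' @param annotations Data frame with columns `metabolite_id`,
#'   `biochemical_name`, `subpathway`, `superpathway`, one row per
#'   metabolite. When `NULL`, every metabolite is annotated "unannotated".
#'
#' @return An object of class `metabolite_table`: a list with elements
#'   `abundances`, `annotations`, `sample_ids`, `metabolite_ids`.
#' @export
metabolite_table <- function(abundances, annotations = NULL) {
  abundances <- as.matrix(abundances)
  if (!is.numeric(abundances)) stop("abundances must be a numeric matrix")
  if (any(abundances < 0, na.rm = TRUE)) stop("abundances must be non-negative")
  if (is.null(colnames(abundances))) {
    colnames(abundances) <- sprintf("M%04d", seq_len(ncol(abundances)))
  }
  if (is.null(rownames(abundances))) {
    rownames(abundances) <- sprintf("S%04d", seq_len(nrow(abundances)))
  }
  if (is.null(annotations)) {
    annotations <- data.frame(
      metabolite_id = colnames(abundances),
      biochemical_name = colnames(abundances),
      subpathway = "unannotated",
      superpathway = "unannotated",
      stringsAsFactors = FALSE
    )
  }
  required <- c("metabolite_id", "biochemical_name", "subpathway", "superpathway")
  missing_cols <- setdiff(required, names(annotations))
  if (length(missing_cols)) {
    stop("annotations lack column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(annotations) != ncol(abundances)) {
    stop("annotations must have one row per metabolite")
  }
  if (!identical(annotations$metabolite_id, colnames(abundances))) {
    stop("annotations$metabolite_id must match abundance column names in order")
  }
  if (any(is.na(annotations$superpathway))) {
    stop("every metabolite needs a superpathway annotation (use \"unannotated\")")
  }
  structure(
    list(
      abundances = abundances,
      annotations = annotations,
      sample_ids = rownames(abundances),
      metabolite_ids = colnames(abundances)
    ),
    class = "metabolite_table"
  )
}

#' @export
dim.metabolite_table <- function(x) dim(x$abundances)

#' @export
print.metabolite_table <- function(x, ...) {
  n_missing <- sum(is.na(x$abundances))
  cat(sprintf(
    "metabolite_table: %d samples x %d metabolites (%d missing cells, %.1f%%)\n",
    nrow(x$abundances), ncol(x$abundances), n_missing,
    100 * n_missing / length(x$abundances)
  ))
  sp <- sort(table(x$annotations$superpathway), decreasing = TRUE)
  cat("superpathways:", paste(sprintf("%s (%d)", names(sp), sp), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a metabolite table
#'
#' @param x A `metabolite_table`.
#' @param samples Sample ids or indices to keep (default all).
#' @param metabolites Metabolite ids or indices to keep (default all).
#' @return A `metabolite_table` restricted to the requested rows/columns.
#' @export
subset_table <- function(x, samples = NULL, metabolites = NULL) {
  stopifnot(inherits(x, "metabolite_table"))
  ab <- x$abundances
  ann <- x$annotations
  if (!is.null(samples)) ab <- ab[samples, , drop = FALSE]
  if (!is.null(metabolites)) {
    ab <- ab[, metabolites, drop = FALSE]
    ann <- ann[match(colnames(ab), ann$metabolite_id), , drop = FALSE]
    rownames(ann) <- NULL
  }
  metabolite_table(ab, ann)
}
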