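#' Write / read cohort artifacts
#'
#' Plain-text serializers for the cohort objects: clinical CSV (one row
#' per subject), metabolite abundance TSV (first column `sample_id`) plus
#' annotation TSV, clamp long-format CSV (columns `subject_id`,
#' `time_min`, `phase`, `F_umol_kg_min`, `C_umol_L`, `enrichment`,
#' `gir_umol_kg_min`), and a truth JSON.
#'
#' @param records Clinical data frame.
#' @param path Output file path.
#' @name cohort_io
NULL

#' @rdname cohort_io
#' @export
write_clinical_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_clinical_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' @rdname cohort_io
#' @param table A [metabolite_table()].
#' @param abundance_path,annotation_path Output TSV paths.
#' @export
write_metabolite_tsv <- function(table, abundance_path, annotation_path) {
  stopifnot(inherits(table, "metabolite_table"))
  ab <- data.frame(sample_id = table$sample_ids, table$abundances,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(ab, abundance_path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  utils::write.table(table$annotations, annotation_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(abundance_path)
}

#' @rdname cohort_io
#' @export
read_metabolite_tsv <- function(abundance_path, annotation_path = NULL) {
  ab <- utils::read.delim(abundance_path, check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(ab[, -1, drop = FALSE])
  rownames(m) <- ab$sample_id
  ann <- if (!is.null(annotation_path)) {
    utils::read.delim(annotation_path, stringsAsFactors = FALSE)
  } else NULL
  metabolite_table(m, ann)
}

#' @rdname cohort_io
#' @param series_list Named list of [clamp_series()].
#' @export
write_clamp_csv <- function(series_list, path) {
  long <- do.call(rbind, lapply(series_list, function(s) {
    data.frame(
      subject_id = s$subject_id, time_min = s$time, phase = s$phase,
      F_umol_kg_min = s$f_inf, C_umol_L = s$conc, enrichment = s$enrich,
      gir_umol_kg_min = s$gir, stringsAsFactors = FALSE
    )
  }))
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_clamp_csv <- function(path) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  out <- lapply(split(long, long$subject_id), function(d) {
    d <- d[order(d$time_min), ]
    clamp_series(d$subject_id[1], d$time_min, d$phase, d$F_umol_kg_min,
                 d$C_umol_L, d$enrichment, d$gir_umol_kg_min)
  })
  out[unique(long$subject_id)]
}

#' @rdname cohort_io
#' @param truth Truth list from [gen_clinical()].
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname cohort_io
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
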