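# Sample-level mixture summaries: detection counts under the censoring
# convention (detections between LOD and LOQ count towards CUP numbers but
# contribute 0 to concentration sums), per-compound detection frequencies
# and concentration statistics, and enumeration of mixture combinations.

sample_key_cols <- function() {
  c("site_id", "system", "matrix", "distance_class", "month_index")
}

records_with_class <- function(table) {
  stopifnot(inherits(table, "residue_table"))
  dplyr::left_join(table$records,
                   table$compounds[, c("compound_id", "pclass")],
                   by = "compound_id")
}

#' Summarise each composite sample
#'
#' One row per (site, matrix, distance class, month) sample. Detected CUPs
#' are records with status `quantified` or `below_loq`; the total
#' concentration sums quantified records only, so a sample full of
#' below-LOQ traces has a positive CUP count and a zero total.
#'
#' @param table A [residue_table()].
#' @return Tibble with the sample key plus `n_cups_detected`,
#'   `n_quantified`, `n_fungicide`, `n_herbicide`, `n_insecticide` and
#'   `total_concentration` (ug/kg).
#' @export
summarize_samples <- function(table) {
  rec <- records_with_class(table)
  det <- rec$detect_status != "not_detected"
  rec$det <- det
  dplyr::summarise(
    dplyr::group_by(rec, dplyr::across(dplyr::all_of(sample_key_cols()))),
    n_cups_detected = sum(.data$det),
    n_quantified = sum(.data$detect_status == "quantified"),
    n_fungicide = sum(.data$det & .data$pclass == "fungicide"),
    n_herbicide = sum(.data$det & .data$pclass == "herbicide"),
    n_insecticide = sum(.data$det & .data$pclass == "insecticide"),
    total_concentration = sum(.data$concentration[
      .data$detect_status == "quantified"]),
    .groups = "drop")
}

n_samples_in_matrix <- function(table, matrix) {
  rec <- table$records[table$records$matrix == matrix, ]
  if (nrow(rec) == 0) {
    stop("no samples for matrix '", matrix, "'", call. = FALSE)
  }
  nrow(dplyr::distinct(rec, dplyr::across(dplyr::all_of(sample_key_cols()))))
}

#' Per-compound detection frequency within one matrix
#'
#' Percentage of samples of the matrix in which the compound was detected
#' (quantified or below LOQ). Compounds never detected are reported with
#' 0%.
#'
#' @param table A [residue_table()].
#' @param matrix `"soil"` or `"vegetation"`.
#' @return Tibble with `compound_id`, `pclass`, `n_detections`,
#'   `detection_frequency` (percent).
#' @export
detection_frequency <- function(table, matrix) {
  n_samples <- n_samples_in_matrix(table, matrix)
  rec <- table$records[table$records$matrix == matrix &
                         table$records$detect_status != "not_detected", ]
  counts <- dplyr::count(rec, .data$compound_id, name = "n_detections")
  out <- dplyr::left_join(table$compounds[, c("compound_id", "pclass")],
                          counts, by = "compound_id")
  out$n_detections[is.na(out$n_detections)] <- 0L
  out$detection_frequency <- 100 * out$n_detections / n_samples
  dplyr::arrange(out, dplyr::desc(.data$detection_frequency),
                 .data$compound_id)
}

#' Per-compound concentration statistics within one matrix
#'
#' Reports both mean variants: `mean_quantified` averages over quantified
#' records only (the headline variant) and `mean_all` divides the same sum
#' by the total number of samples of the matrix. Compounds with no
#' quantified record are absent from the output (their statistics are
#' undefined, even when they were detected below LOQ).
#'
#' @inheritParams detection_frequency
#' @return Tibble with `compound_id`, `n_quantified`, `mean_quantified`,
#'   `mean_all`, `max_concentration` (all ug/kg).
#' @export
concentration_stats <- function(table, matrix) {
  n_samples <- n_samples_in_matrix(table, matrix)
  rec <- table$records[table$records$matrix == matrix &
                         table$records$detect_status == "quantified", ]
  if (nrow(rec) == 0) {
    return(tibble::tibble(compound_id = character(), n_quantified = integer(),
                          mean_quantified = numeric(), mean_all = numeric(),
                          max_concentration = numeric()))
  }
  out <- dplyr::summarise(
    dplyr::group_by(rec, .data$compound_id),
    n_quantified = dplyr::n(),
    mean_quantified = mean(.data$concentration),
    total = sum(.data$concentration),
    max_concentration = max(.data$concentration),
    .groups = "drop")
  out$mean_all <- out$total / n_samples
  out$total <- NULL
  dplyr::arrange(out[, c("compound_id", "n_quantified", "mean_quantified",
                         "mean_all", "max_concentration")],
                 .data$compound_id)
}

#' Enumerate mixture combinations within one matrix
#'
#' A mixture is the order-independent set of compounds detected (quantified
#' or below LOQ) in one sample. Samples without any detection are excluded
#' from the enumeration and reported separately. Ties for the most frequent
#' mixture are broken lexicographically on the mixture key.
#'
#' @inheritParams detection_frequency
#' @return A list of class `mixture_enumeration` with elements `n_unique`,
#'   `counts` (tibble: `mixture_key`, `n_compounds`, `has_insecticide`,
#'   `n_samples`), `n_with_insecticide` (unique mixtures containing at
#'   least one insecticide), `most_frequent` (list with `mixture_key`,
#'   `compounds`, `n_samples`) and `n_empty_samples`.
#' @export
enumerate_mixtures <- function(table, matrix) {
  n_samples <- n_samples_in_matrix(table, matrix)
  rec <- records_with_class(table)
  rec <- rec[rec$matrix == matrix & rec$detect_status != "not_detected", ]
  mixes <- dplyr::summarise(
    dplyr::group_by(rec, dplyr::across(dplyr::all_of(sample_key_cols()))),
    mixture_key = paste(sort(unique(.data$compound_id)), collapse = "|"),
    n_compounds = dplyr::n_distinct(.data$compound_id),
    has_insecticide = any(.data$pclass == "insecticide"),
    .groups = "drop")
  counts <- dplyr::summarise(
    dplyr::group_by(mixes, .data$mixture_key, .data$n_compounds,
                    .data$has_insecticide),
    n_samples = dplyr::n(), .groups = "drop")
  counts <- dplyr::arrange(counts, dplyr::desc(.data$n_samples),
                           .data$mixture_key)
  most <- if (nrow(counts)) {
    list(mixture_key = counts$mixture_key[1],
         compounds = strsplit(counts$mixture_key[1], "|", fixed = TRUE)[[1]],
         n_samples = counts$n_samples[1])
  } else NULL
  structure(
    list(n_unique = nrow(counts),
         counts = counts,
         n_with_insecticide = sum(counts$has_insecticide),
         most_frequent = most,
         n_empty_samples = n_samples - nrow(mixes)),
    class = "mixture_enumeration")
}

#' @export
print.mixture_enumeration <- function(x, ...) {
  cat(sprintf(
    "<mixture_enumeration> %d unique mixtures (%d with >= 1 insecticide), %d empty samples\n",
    x$n_unique, x$n_with_insecticide, x$n_empty_samples))
  if (!is.null(x$most_frequent)) {
    cat(sprintf("most frequent (%d samples): %s\n",
                x$most_frequent$n_samples, x$most_frequent$mixture_key))
  }
  invisible(x)
}
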