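# Data model for residue campaigns: long-format residue records, compound
# metadata and ecotoxicological endpoints, with fixed internal units
# (concentrations in ug/kg dry weight = ng/g; soil endpoints in mg/kg;
# bee contact LD50 in ng/bee).

#' Controlled vocabularies of the residue data model
#'
#' Management systems, sample matrices, distance classes, pesticide classes
#' and detection statuses used throughout the package. `month_index` runs
#' 0..12 over the thirteen monthly campaigns of a full sampling year
#' (February of year one through February of year two); calendar parsing is
#' a reader concern only.
#'
#' Distance classes map in-field samples (taken 20 m inside the cultivated
#' area) to distance 0 m and the off-field meadow samples to 1, 5 and 20 m
#' from the field margin; see [map_distance()].
#'
#' @return A character vector of allowed values.
#' @seealso [residue_table()], [map_distance()]
#' @export
cup_systems <- function() c("arable", "vegetable", "viticulture")

#' @rdname cup_systems
#' @export
cup_matrices <- function() c("soil", "vegetation")

#' @rdname cup_systems
#' @export
cup_distance_classes <- function() c("in_field", "m1", "m5", "m20")

#' @rdname cup_systems
#' @export
cup_pesticide_classes <- function() c("fungicide", "herbicide", "insecticide")

#' @rdname cup_systems
#' @export
cup_detect_status <- function() c("not_detected", "below_loq", "quantified")

#' Month labels for the 0..12 month index
#'
#' @param start_year First calendar year of the campaign (February of this
#'   year is month index 0).
#' @return Character vector of length 13, e.g. `"Feb 2021" ... "Feb 2022"`.
#' @export
month_labels <- function(start_year = 2021) {
  mons <- c("Feb", "Mar", "Apr", "May", "Jun", "Jul", "Aug", "Sep", "Oct",
            "Nov", "Dec", "Jan", "Feb")
  yrs <- c(rep(start_year, 11), start_year + 1, start_year + 1)
  paste(mons, yrs)
}

residue_record_cols <- function() {
  c("site_id", "system", "matrix", "distance_class", "month_index",
    "compound_id", "concentration", "detect_status", "loq", "lod")
}

fail_rows <- function(bad, what) {
  if (any(bad)) {
    idx <- utils::head(which(bad), 5L)
    stop(sprintf("%s (rows: %s%s)", what, paste(idx, collapse = ", "),
                 if (sum(bad) > 5L) ", ..." else ""), call. = FALSE)
  }
  invisible(TRUE)
}

#' Construct a compound metadata table
#'
#' @param compound_id Short stable tokens, unique.
#' @param name Free-text compound names (defaults to `compound_id`).
#' @param pclass Pesticide class, one of
#'   `"fungicide"`, `"herbicide"`, `"insecticide"`.
#' @return A validated tibble with class `cup_compounds`.
#' @export
compound_table <- function(compound_id, name = compound_id, pclass) {
  out <- tibble::tibble(compound_id = as.character(compound_id),
                        name = as.character(name),
                        pclass = as.character(pclass))
  validate_compound_table(out)
}

validate_compound_table <- function(x) {
  x <- tibble::as_tibble(x)
  need <- c("compound_id", "pclass")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop("compound table is missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"name" %in% names(x)) x$name <- x$compound_id
  if (anyDuplicated(x$compound_id)) {
    stop("duplicated compound_id in compound table", call. = FALSE)
  }
  fail_rows(!x$pclass %in% cup_pesticide_classes(),
            "pclass must be fungicide, herbicide or insecticide")
  class(x) <- c("cup_compounds", class(tibble::tibble()))
  x[, c("compound_id", "name", "pclass")]
}

#' Construct a validated residue table
#'
#' The residue table is the pipeline's universal input: one row per
#' (site, matrix, distance class, month, compound) measurement with explicit
#' left-censoring semantics. A record is `"quantified"` if and only if its
#' concentration is at or above the LOQ; detections between LOD and LOQ are
#' `"below_loq"` and carry concentration 0 for all concentration arithmetic
#' (the detection still counts towards CUP numbers); `"not_detected"` rows
#' also carry concentration 0.
#'
#' @param records Data frame with columns `site_id`, `system`, `matrix`,
#'   `distance_class`, `month_index`, `compound_id`, `concentration`
#'   (ug/kg dry weight), `detect_status`, `loq`, `lod` (both ug/kg, > 0).
#' @param compounds Compound metadata, see [compound_table()].
#' @return An object of class `residue_table`: a list with elements
#'   `records` and `compounds`.
#' @export
residue_table <- function(records, compounds) {
  records <- tibble::as_tibble(records)
  compounds <- validate_compound_table(compounds)
  miss <- setdiff(residue_record_cols(), names(records))
  if (length(miss)) {
    stop("residue records are missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  records <- records[, residue_record_cols()]
  records$month_index <- as.integer(records$month_index)

  fail_rows(!records$system %in% cup_systems(), "invalid system")
  fail_rows(!records$matrix %in% cup_matrices(), "invalid matrix")
  fail_rows(!records$distance_class %in% cup_distance_classes(),
            "invalid distance_class")
  fail_rows(!records$detect_status %in% cup_detect_status(),
            "invalid detect_status")
  fail_rows(is.na(records$month_index) | records$month_index < 0L,
            "month_index must be a non-negative integer")
  fail_rows(is.na(records$concentration) | records$concentration < 0,
            "concentration must be >= 0")
  fail_rows(is.na(records$loq) | records$loq <= 0, "loq must be > 0")
  fail_rows(is.na(records$lod) | records$lod <= 0, "lod must be > 0")
  fail_rows(records$lod > records$loq, "lod must not exceed loq")
  # censoring semantics: quantified <=> concentration >= loq; censored rows 0
  quant <- records$detect_status == "quantified"
  fail_rows(quant & records$concentration < records$loq,
            "quantified records must have concentration >= loq")
  fail_rows(!quant & records$concentration != 0,
            "not_detected/below_loq records must carry concentration 0")
  fail_rows(!records$compound_id %in% compounds$compound_id,
            "compound_id missing from compound table")
  key <- do.call(paste, c(records[c("site_id", "matrix", "distance_class",
                                    "month_index", "compound_id")],
                          sep = "\r"))
  fail_rows(duplicated(key),
            "duplicate (site, matrix, distance_class, month, compound) key")

  structure(list(records = records, compounds = compounds),
            class = "residue_table")
}

#' @export
print.residue_table <- function(x, ...) {
  r <- x$records
  det <- sum(r$detect_status != "not_detected")
  cat(sprintf(
    "<residue_table> %d records | %d compounds | %d samples | %d detections (%d quantified)\n",
    nrow(r), nrow(x$compounds),
    nrow(dplyr::distinct(r, .data$site_id, .data$matrix,
                         .data$distance_class, .data$month_index)),
    det, sum(r$detect_status == "quantified")))
  invisible(x)
}

# canonical external column names -> internal names
residue_col_map <- function() {
  c(site_id = "site_id", system = "system", matrix = "matrix",
    distance_class = "distance_class", month_index = "month",
    compound_id = "compound_id", concentration = "concentration_ug_kg",
    detect_status = "detect_status", loq = "loq_ug_kg", lod = "lod_ug_kg")
}

apply_schema <- function(df, col_map, schema = NULL, what = "table") {
  wanted <- vapply(names(col_map), function(nm) {
    if (!is.null(schema) && nm %in% names(schema)) schema[[nm]] else col_map[[nm]]
  }, character(1))
  miss <- setdiff(unname(wanted), names(df))
  if (length(miss)) {
    stop(sprintf("%s is missing required columns: %s", what,
                 paste(miss, collapse = ", ")), call. = FALSE)
  }
  out <- df[, unname(wanted)]
  names(out) <- names(col_map)
  out
}

#' Read and write residue tables in the canonical CSV dialect
#'
#' The canonical dialect is UTF-8 comma-separated with a header row and
#' columns `site_id, system, matrix, distance_class, month, compound_id,
#' concentration_ug_kg, detect_status, loq_ug_kg, lod_ug_kg`. A `schema`
#' mapping allows reading files with other column names without editing
#' them: a named character vector from canonical names (use the internal
#' names `site_id`, `system`, `matrix`, `distance_class`, `month_index`,
#' `compound_id`, `concentration`, `detect_status`, `loq`, `lod`) to the
#' file's column names.
#'
#' @param path Path to the residue CSV.
#' @param compounds A compound table, or a path to a compound CSV with
#'   columns `compound_id, name, pclass`.
#' @param schema Optional named character vector mapping internal column
#'   names to the file's column names.
#' @return [read_residue_table()] returns a validated [residue_table()];
#'   the writers return their `path` invisibly.
#' @export
read_residue_table <- function(path, compounds, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.character(compounds)) compounds <- read_compound_table(compounds)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  rec <- apply_schema(raw, residue_col_map(), schema, what = "residue table")
  residue_table(rec, compounds)
}

#' @param table A [residue_table()].
#' @rdname read_residue_table
#' @export
write_residue_table <- function(table, path) {
  stopifnot(inherits(table, "residue_table"))
  out <- table$records
  names(out) <- unname(residue_col_map())[match(names(out),
                                                names(residue_col_map()))]
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname read_residue_table
#' @export
read_compound_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  cmap <- c(compound_id = "compound_id", name = "name", pclass = "pclass")
  if (!"name" %in% names(raw) && is.null(schema)) raw$name <- raw$compound_id
  validate_compound_table(apply_schema(raw, cmap, schema, "compound table"))
}

#' @rdname read_residue_table
#' @export
write_compound_table <- function(compounds, path) {
  readr::write_csv(tibble::as_tibble(validate_compound_table(compounds)),
                   path, progress = FALSE)
  invisible(path)
}

#' Per-compound ecotoxicological endpoint tables
#'
#' Endpoints drive PNEC derivation and hazard quotients: chronic NOECs for
#' collembola and earthworms and an earthworm LC50 (all mg/kg soil), and an
#' acute honey-bee contact LD50 (canonically ng active ingredient per bee).
#' Absent endpoints are `NA`, never 0; a compound without a usable endpoint
#' is excluded from mixture sums and reduces the reported coverage.
#'
#' The canonical CSV columns are `compound_id, noec_collembola_mg_kg,
#' noec_earthworm_mg_kg, lc50_earthworm_mg_kg, ld50_bee, ld50_unit, source`.
#' `ld50_unit` may be `"ng_per_bee"` (default) or `"ug_per_bee"`; values
#' declared in ug/bee are converted to ng/bee (x 1000) at read time.
#'
#' @param path Path to the endpoint CSV.
#' @param schema Optional named character vector mapping internal column
#'   names (`compound_id`, `noec_collembola`, `noec_earthworm`,
#'   `lc50_earthworm`, `ld50_bee`) to the file's column names.
#' @return A tibble of class `endpoint_table` with columns `compound_id`,
#'   `noec_collembola`, `noec_earthworm`, `lc50_earthworm` (mg/kg),
#'   `ld50_bee` (ng/bee) and `source`.
#' @export
read_endpoint_table <- function(path, schema = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0) return(endpoint_table(tibble::tibble(compound_id = character())))
  cmap <- c(compound_id = "compound_id",
            noec_collembola = "noec_collembola_mg_kg",
            noec_earthworm = "noec_earthworm_mg_kg",
            lc50_earthworm = "lc50_earthworm_mg_kg",
            ld50_bee = "ld50_bee")
  for (cn in setdiff(unname(cmap), names(raw))) raw[[cn]] <- NA_real_
  out <- apply_schema(raw, cmap, schema, "endpoint table")
  unit <- if ("ld50_unit" %in% names(raw)) raw$ld50_unit else "ng_per_bee"
  unit[is.na(unit)] <- "ng_per_bee"
  if (!all(unit %in% c("ng_per_bee", "ug_per_bee"))) {
    stop("ld50_unit must be ng_per_bee or ug_per_bee", call. = FALSE)
  }
  out$ld50_bee <- out$ld50_bee * ifelse(unit == "ug_per_bee", 1000, 1)
  out$source <- if ("source" %in% names(raw)) raw$source else NA_character_
  endpoint_table(out)
}

#' @param x Data frame of endpoints in canonical units.
#' @rdname read_endpoint_table
#' @export
endpoint_table <- function(x) {
  x <- tibble::as_tibble(x)
  if (!"compound_id" %in% names(x)) {
    stop("endpoint table needs a compound_id column", call. = FALSE)
  }
  for (cn in c("noec_collembola", "noec_earthworm", "lc50_earthworm",
               "ld50_bee")) {
    if (!cn %in% names(x)) x[[cn]] <- NA_real_
    fail_rows(!is.na(x[[cn]]) & x[[cn]] <= 0,
              sprintf("endpoint %s must be > 0 when present", cn))
  }
  if (!"source" %in% names(x)) x$source <- NA_character_
  if (anyDuplicated(x$compound_id)) {
    stop("duplicated compound_id in endpoint table", call. = FALSE)
  }
  out <- x[, c("compound_id", "noec_collembola", "noec_earthworm",
               "lc50_earthworm", "ld50_bee", "source")]
  class(out) <- c("endpoint_table", class(tibble::tibble()))
  out
}

#' @param endpoints An `endpoint_table`.
#' @rdname read_endpoint_table
#' @export
write_endpoint_table <- function(endpoints, path) {
  out <- tibble::as_tibble(endpoints)
  names(out)[match(c("noec_collembola", "noec_earthworm", "lc50_earthworm"),
                   names(out))] <-
    c("noec_collembola_mg_kg", "noec_earthworm_mg_kg", "lc50_earthworm_mg_kg")
  out$ld50_unit <- "ng_per_bee"
  readr::write_csv(out, path, progress = FALSE)
  invisible(path)
}
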