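# End-to-end orchestration: simulate (or read) a campaign, then run the
# summary, temporal, spatial and risk stages, writing tidy CSV outputs and
# a JSON manifest with a content hash per file. Identical configuration and
# seed yield an identical manifest.

#' Configure a pipeline run
#'
#' Defaults reproduce the analysis constants: peak-detection delta 0.3,
#' probability floor 1e-6, bee soil contact 2.23 g, surrogate LD50 divisor
#' 10, assessment factors 10 (NOEC) and 1000 (LC50).
#'
#' @param out_dir Output directory (created if needed).
#' @param seed Seed for the synthetic stage.
#' @param stages Stages to run, in dependency order, a subset of
#'   `c("simulate", "summarize", "temporal", "spatial", "risk")`. Without
#'   `"simulate"`, `residue_path` and `compound_path` must point to
#'   existing CSVs.
#' @param synthetic A [synthetic_config()]; built from `seed` when `NULL`.
#' @param residue_path,compound_path,endpoint_path Input CSVs for runs on
#'   measured data; `endpoint_path = "synthetic"` uses
#'   [synthetic_endpoints()].
#' @param schema Optional reader schema (see [read_residue_table()]).
#' @param span Loess span (`NULL` = leave-one-out selection),
#'   `candidate_spans` its grid, `epsilon` the probability floor, `delta`
#'   the peak threshold.
#' @param statistic Per-sample statistic for the temporal and spatial
#'   stages.
#' @param c_background,include_infield Distance-decay settings, see
#'   [fit_exponential()].
#' @param soil_contact,surrogate_divisor,af_noec,af_lc50 Risk settings.
#' @return A list of class `run_config`.
#' @export
pipeline_config <- function(out_dir, seed = 1L,
                            stages = c("simulate", "summarize", "temporal",
                                       "spatial", "risk"),
                            synthetic = NULL,
                            residue_path = NULL, compound_path = NULL,
                            endpoint_path = "synthetic", schema = NULL,
                            span = NULL,
                            candidate_spans = seq(0.3, 1, by = 0.1),
                            epsilon = 1e-6, delta = 0.3,
                            statistic = "n_cups_detected",
                            c_background = "far", include_infield = TRUE,
                            soil_contact = 2.23, surrogate_divisor = 10,
                            af_noec = 10, af_lc50 = 1000) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(out_dir = out_dir, seed = as.integer(seed), stages = stages,
                 synthetic = synthetic %||% synthetic_config(seed = seed),
                 residue_path = residue_path, compound_path = compound_path,
                 endpoint_path = endpoint_path, schema = schema,
                 span = span, candidate_spans = candidate_spans,
                 epsilon = epsilon, delta = delta, statistic = statistic,
                 c_background = c_background,
                 include_infield = include_infield,
                 soil_contact = soil_contact,
                 surrogate_divisor = surrogate_divisor,
                 af_noec = af_noec, af_lc50 = af_lc50),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key/value file with the argument names of [pipeline_config()];
#' unknown keys are rejected.
#'
#' @param path YAML file.
#' @param out_dir Overrides the file's `out_dir` when given.
#' @return A `run_config`.
#' @export
read_pipeline_config <- function(path, out_dir = NULL) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (!is.null(out_dir)) vals$out_dir <- out_dir
  do.call(pipeline_config, vals)
}

write_output <- function(df, dir, name) {
  path <- file.path(dir, name)
  readr::write_csv(tibble::as_tibble(df), path, progress = FALSE)
  path
}

#' Run the analysis pipeline
#'
#' Executes the configured stages in dependency order and writes tidy CSV
#' outputs plus `manifest.json` listing every output file with its MD5
#' content hash and the resolved settings. A failed or unrunnable stage is
#' recorded in the manifest (with a warning) and the remaining stages still
#' run; the risk stage is skipped with a warning when no endpoint table is
#' available.
#'
#' @param config A `run_config` from [pipeline_config()].
#' @return The manifest (invisibly): list with `settings`, `outputs`
#'   (tibble `file`, `md5`), `stages_run`, `stages_failed`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  failed <- character(0)
  ran <- character(0)

  table <- NULL
  if ("simulate" %in% config$stages) {
    sim <- generate_campaign(config$synthetic)
    table <- sim$table
    outputs <- c(outputs,
                 write_residue_table(table,
                                     file.path(config$out_dir, "residues.csv")),
                 write_compound_table(table$compounds,
                                      file.path(config$out_dir, "compounds.csv")))
    ran <- c(ran, "simulate")
  } else {
    if (is.null(config$residue_path) || is.null(config$compound_path)) {
      stop("without the simulate stage, residue_path and compound_path are required",
           call. = FALSE)
    }
    table <- read_residue_table(config$residue_path, config$compound_path,
                                schema = config$schema)
  }

  run_stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    res <- tryCatch(fun(), error = function(e) e)
    if (inherits(res, "error")) {
      warning("stage '", name, "' failed: ", conditionMessage(res),
              call. = FALSE)
      failed <<- c(failed, name)
    } else {
      outputs <<- c(outputs, res)
      ran <<- c(ran, name)
    }
    invisible(NULL)
  }

  run_stage("summarize", function() {
    out <- write_output(summarize_samples(table), config$out_dir,
                        "sample_summary.csv")
    for (m in intersect(cup_matrices(), unique(table$records$matrix))) {
      out <- c(out,
               write_output(detection_frequency(table, m), config$out_dir,
                            sprintf("detection_frequency_%s.csv", m)),
               write_output(concentration_stats(table, m), config$out_dir,
                            sprintf("concentration_stats_%s.csv", m)))
      mix <- enumerate_mixtures(table, m)
      out <- c(out, write_output(mix$counts, config$out_dir,
                                 sprintf("mixtures_%s.csv", m)))
    }
    out
  })

  run_stage("temporal", function() {
    out <- character(0)
    for (m in intersect(cup_matrices(), unique(table$records$matrix))) {
      k <- compare_systems(table, m, "in_field", config$statistic,
                           span = config$span,
                           candidate_spans = config$candidate_spans,
                           epsilon = config$epsilon)
      kd <- tibble::as_tibble(as.data.frame(as.table(k)))
      names(kd) <- c("from_system", "to_system", "kl_bits")
      out <- c(out, write_output(kd, config$out_dir,
                                 sprintf("kl_divergence_%s.csv", m)))
      peaks <- dplyr::bind_rows(lapply(
        sort(unique(table$records$system)), function(s) {
          ms <- monthly_series(table, m, "in_field", config$statistic)
          ser <- ms[ms$system == s, c("month_index", "value")]
          ser <- detrend_linear(ser)
          pk <- detect_peaks(ser$value, delta = config$delta,
                             positions = ser$month_index)
          if (nrow(pk)) cbind(tibble::tibble(system = s, matrix = m), pk)
          else NULL
        }))
      if (!is.null(peaks) && nrow(peaks)) {
        out <- c(out, write_output(peaks, config$out_dir,
                                   sprintf("peaks_%s.csv", m)))
      }
    }
    out
  })

  run_stage("spatial", function() {
    fits <- dplyr::bind_rows(lapply(
      intersect(cup_matrices(), unique(table$records$matrix)),
      function(m) fit_distance_decay(table, m, config$statistic,
                                     config$c_background,
                                     config$include_infield)))
    write_output(fits, config$out_dir, "distance_decay.csv")
  })

  run_stage("risk", function() {
    endpoints <- if (identical(config$endpoint_path, "synthetic")) {
      synthetic_endpoints()
    } else if (!is.null(config$endpoint_path) &&
               file.exists(config$endpoint_path)) {
      read_endpoint_table(config$endpoint_path)
    } else {
      stop("no endpoint table available")
    }
    out <- character(0)
    for (org in c("collembola", "earthworm")) {
      rt <- risk_table(table, endpoints, org, matrix = "soil",
                       af_noec = config$af_noec, af_lc50 = config$af_lc50)
      out <- c(out,
               write_output(rt, config$out_dir,
                            sprintf("risk_samples_%s.csv", org)),
               write_output(suppressWarnings(aggregate_risk(rt, "mrq")),
                            config$out_dir,
                            sprintf("risk_aggregated_%s.csv", org)))
    }
    ht <- hazard_table(table, endpoints, matrix = "soil",
                       soil_contact = config$soil_contact,
                       surrogate_divisor = config$surrogate_divisor)
    c(out,
      write_output(ht, config$out_dir, "hazard_samples_bee.csv"),
      write_output(suppressWarnings(aggregate_risk(ht, "mhq")),
                   config$out_dir, "hazard_aggregated_bee.csv"))
  })

  settings <- unclass(config)
  settings$synthetic <- NULL      # tables are not scalar settings
  settings <- settings[!vapply(settings, is.null, logical(1))]
  manifest <- list(
    settings = settings,
    synthetic_seed = config$synthetic$seed,
    outputs = tibble::tibble(file = basename(outputs),
                             md5 = unname(tools::md5sum(outputs))),
    stages_run = ran,
    stages_failed = failed)
  jsonlite::write_json(
    list(settings = manifest$settings,
         synthetic_seed = manifest$synthetic_seed,
         outputs = manifest$outputs,
         stages_run = manifest$stages_run,
         stages_failed = manifest$stages_failed),
    file.path(config$out_dir, "manifest.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
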