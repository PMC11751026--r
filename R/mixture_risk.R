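# Additive mixture risk and hazard quotients. For soil organisms the risk
# quotient of a compound is RQ = MEC / PNEC with PNEC = NOEC / 10 (or
# LC50 / 1000 when no NOEC exists) and the mixture risk quotient is the
# additive sum MRQ = sum(RQ) over the compounds of one sample. For a
# surrogate ground-nesting bee the contact hazard quotient is
# HQ = (soil contact mass [g] * MEC [ng/g]) / (honey-bee contact LD50 / 10
# [ng/bee]) and MHQ = sum(HQ); MHQ > 1 flags a potential lethal hazard.
# Below-LOQ detections carry concentration 0 and contribute nothing to the
# sums but still count towards coverage; compounds without a usable
# endpoint are excluded (never imputed) and reduce coverage.

#' Predicted no-effect concentrations from NOEC/LC50 endpoints
#'
#' PNEC = NOEC / 10 when a chronic NOEC exists, else LC50 / 1000
#' (earthworms only; collembola endpoints are NOEC-based). Compounds with
#' no usable endpoint get `NA` and are excluded from mixture sums.
#'
#' @param endpoints An `endpoint_table` (see [read_endpoint_table()]).
#' @param organism `"collembola"` or `"earthworm"`.
#' @param af_noec,af_lc50 Assessment factors (defaults 10 and 1000).
#' @return Tibble with `compound_id`, `pnec_mg_kg`, `endpoint_kind`.
#' @export
pnec <- function(endpoints, organism = c("collembola", "earthworm"),
                 af_noec = 10, af_lc50 = 1000) {
  organism <- match.arg(organism)
  stopifnot(af_noec > 0, af_lc50 > 0)
  e <- tibble::as_tibble(endpoints)
  noec <- switch(organism, collembola = e$noec_collembola,
                 earthworm = e$noec_earthworm)
  lc50 <- if (organism == "earthworm") e$lc50_earthworm else
    rep(NA_real_, nrow(e))
  kind <- ifelse(!is.na(noec), "NOEC", ifelse(!is.na(lc50), "LC50",
                                              NA_character_))
  tibble::tibble(
    compound_id = e$compound_id,
    pnec_mg_kg = ifelse(!is.na(noec), noec / af_noec,
                        ifelse(!is.na(lc50), lc50 / af_lc50, NA_real_)),
    endpoint_kind = kind)
}

#' Categorise a mixture risk quotient
#'
#' Left-closed bands: negligible `[0, 0.01)`, low `[0.01, 0.1)`, medium
#' `[0.1, 1)`, high at exactly 1, very high above 1.
#'
#' @param mrq Non-negative numeric vector.
#' @return Character vector of categories.
#' @export
categorize_mrq <- function(mrq) {
  if (any(!is.finite(mrq)) || any(mrq < 0)) {
    stop("MRQ must be finite and >= 0", call. = FALSE)
  }
  ifelse(mrq < 0.01, "negligible",
         ifelse(mrq < 0.1, "low",
                ifelse(mrq < 1, "medium",
                       ifelse(mrq == 1, "high", "very_high"))))
}

#' Additive mixture risk quotient of one sample
#'
#' Computes per-compound risk quotients RQ = MEC / PNEC (MEC in ug/kg,
#' PNEC converted from mg/kg to ug/kg before division) for the quantified
#' compounds of one composite sample and sums them into the MRQ. Below-LOQ
#' detections contribute 0. Coverage is the fraction of detected compounds
#' with a usable endpoint.
#'
#' @param records Rows of one sample: columns `compound_id`,
#'   `concentration` (ug/kg), `detect_status`.
#' @param endpoints An `endpoint_table`.
#' @param organism `"collembola"` or `"earthworm"`.
#' @param af_noec,af_lc50 Assessment factors, see [pnec()].
#' @return A list of class `risk_result`: `rq` (named vector over detected
#'   compounds with an endpoint), `mrq`, `rq_max`, `rq_max_compound`,
#'   `frac_rq_max` (0 when MRQ is 0), `category`, `coverage`,
#'   `n_detected`.
#' @export
sample_mrq <- function(records, endpoints,
                       organism = c("collembola", "earthworm"),
                       af_noec = 10, af_lc50 = 1000) {
  organism <- match.arg(organism)
  pn <- pnec(endpoints, organism, af_noec, af_lc50)
  det <- records[records$detect_status != "not_detected", ]
  pnec_mg <- pn$pnec_mg_kg[match(det$compound_id, pn$compound_id)]
  usable <- !is.na(pnec_mg)
  rq <- det$concentration[usable] / (pnec_mg[usable] * 1000)
  names(rq) <- det$compound_id[usable]
  mrq <- sum(rq)
  rq_max <- if (length(rq)) max(rq) else 0
  structure(list(
    rq = rq,
    mrq = mrq,
    rq_max = rq_max,
    rq_max_compound = if (length(rq) && rq_max > 0)
      names(rq)[which.max(rq)] else NA_character_,
    frac_rq_max = if (mrq > 0) rq_max / mrq else 0,
    category = categorize_mrq(mrq),
    coverage = if (nrow(det)) sum(usable) / nrow(det) else NA_real_,
    n_detected = nrow(det),
    organism = organism), class = "risk_result")
}

#' Contact hazard quotient for a surrogate ground-nesting bee
#'
#' `HQ = (soil_contact * mec) / (ld50_bee / surrogate_divisor)`, all mass
#' terms in ng: the MEC in ng/g (= ug/kg) times the soil mass contacted
#' during burrowing (default 2.23 g over 48 h), against a surrogate
#' solitary-bee LD50 derived from the honey-bee contact LD50 divided by 10.
#'
#' @param mec Measured concentration, ng/g (>= 0).
#' @param ld50_bee Honey-bee contact LD50, ng/bee (> 0).
#' @param soil_contact Soil mass contacted, g (default 2.23).
#' @param surrogate_divisor Honey-bee-to-solitary-bee safety divisor
#'   (default 10).
#' @return Dimensionless hazard quotient.
#' @export
bee_hq <- function(mec, ld50_bee, soil_contact = 2.23,
                   surrogate_divisor = 10) {
  if (any(!is.finite(ld50_bee)) || any(ld50_bee <= 0)) {
    stop("ld50_bee must be > 0", call. = FALSE)
  }
  if (any(mec < 0)) stop("mec must be >= 0", call. = FALSE)
  (soil_contact * mec) / (ld50_bee / surrogate_divisor)
}

#' Additive mixture hazard quotient of one sample
#'
#' Sums [bee_hq()] over the quantified compounds of one sample; compounds
#' without a bee LD50 are excluded and reduce coverage. The hazard flag is
#' strict: `mhq > 1`.
#'
#' @inheritParams sample_mrq
#' @inheritParams bee_hq
#' @return A list of class `hazard_result`: `hq` (named vector), `mhq`,
#'   `hq_max`, `hq_max_compound`, `frac_hq_max`, `hazard`, `coverage`,
#'   `n_detected`.
#' @export
sample_mhq <- function(records, endpoints, soil_contact = 2.23,
                       surrogate_divisor = 10) {
  e <- tibble::as_tibble(endpoints)
  det <- records[records$detect_status != "not_detected", ]
  ld50 <- e$ld50_bee[match(det$compound_id, e$compound_id)]
  usable <- !is.na(ld50)
  hq <- bee_hq(det$concentration[usable], ld50[usable], soil_contact,
               surrogate_divisor)
  names(hq) <- det$compound_id[usable]
  mhq <- sum(hq)
  hq_max <- if (length(hq)) max(hq) else 0
  structure(list(
    hq = hq, mhq = mhq, hq_max = hq_max,
    hq_max_compound = if (length(hq) && hq_max > 0)
      names(hq)[which.max(hq)] else NA_character_,
    frac_hq_max = if (mhq > 0) hq_max / mhq else 0,
    hazard = mhq > 1,
    coverage = if (nrow(det)) sum(usable) / nrow(det) else NA_real_,
    n_detected = nrow(det),
    soil_contact = soil_contact,
    surrogate_divisor = surrogate_divisor), class = "hazard_result")
}

risk_sample_groups <- function(table, matrix) {
  rec <- table$records[table$records$matrix == matrix, ]
  if (nrow(rec) == 0) stop("no samples for matrix '", matrix, "'",
                           call. = FALSE)
  key <- do.call(paste, c(rec[sample_key_cols()], sep = "\r"))
  split(rec, factor(key, levels = unique(key)))
}

#' Per-sample mixture risk over a residue table
#'
#' Applies [sample_mrq()] to every composite sample of one matrix.
#'
#' @param table A [residue_table()].
#' @param endpoints An `endpoint_table`.
#' @param organism `"collembola"` or `"earthworm"`.
#' @param matrix Matrix to assess; the soil-exposure scenario applies to
#'   `"soil"` (the default).
#' @inheritParams pnec
#' @return Tibble with the sample key plus `organism`, `mrq`, `rq_max`,
#'   `rq_max_compound`, `frac_rq_max`, `category`, `coverage`,
#'   `n_detected`.
#' @export
risk_table <- function(table, endpoints,
                       organism = c("collembola", "earthworm"),
                       matrix = "soil", af_noec = 10, af_lc50 = 1000) {
  organism <- match.arg(organism)
  groups <- risk_sample_groups(table, matrix)
  rows <- lapply(groups, function(g) {
    r <- sample_mrq(g, endpoints, organism, af_noec, af_lc50)
    cbind(g[1, sample_key_cols()],
          tibble::tibble(organism = organism, mrq = r$mrq,
                         rq_max = r$rq_max,
                         rq_max_compound = r$rq_max_compound,
                         frac_rq_max = r$frac_rq_max,
                         category = r$category, coverage = r$coverage,
                         n_detected = r$n_detected))
  })
  tibble::as_tibble(do.call(rbind, unname(rows)))
}

#' Per-sample bee contact hazard over a residue table
#'
#' Applies [sample_mhq()] to every composite sample of one matrix.
#'
#' @inheritParams risk_table
#' @inheritParams bee_hq
#' @return Tibble with the sample key plus `mhq`, `hq_max`,
#'   `hq_max_compound`, `frac_hq_max`, `hazard`, `coverage`, `n_detected`.
#' @export
hazard_table <- function(table, endpoints, matrix = "soil",
                         soil_contact = 2.23, surrogate_divisor = 10) {
  groups <- risk_sample_groups(table, matrix)
  rows <- lapply(groups, function(g) {
    r <- sample_mhq(g, endpoints, soil_contact, surrogate_divisor)
    cbind(g[1, sample_key_cols()],
          tibble::tibble(mhq = r$mhq, hq_max = r$hq_max,
                         hq_max_compound = r$hq_max_compound,
                         frac_hq_max = r$frac_hq_max, hazard = r$hazard,
                         coverage = r$coverage, n_detected = r$n_detected))
  })
  tibble::as_tibble(do.call(rbind, unname(rows)))
}

#' Aggregate per-sample risk over replicate sites
#'
#' Arithmetic mean and maximum of a per-sample quotient over the replicate
#' sites of each (system, matrix, distance class, month) cell -- the shape
#' of the per-month risk overview tables. Cells with fewer than `n_reps`
#' replicates are flagged, cells with zero replicates are absent.
#'
#' @param results Output of [risk_table()] or [hazard_table()].
#' @param value Column to aggregate (`"mrq"` or `"mhq"`).
#' @param n_reps Expected number of replicate sites (default 3).
#' @return Tibble with grouping columns plus `mean_value`, `max_value`,
#'   `n_sites`, `complete`, and for MRQ aggregation `mean_category` /
#'   `max_category`.
#' @export
aggregate_risk <- function(results, value = c("mrq", "mhq"), n_reps = 3) {
  value <- match.arg(value)
  if (!value %in% names(results)) stop("column '", value, "' not found",
                                       call. = FALSE)
  grp <- intersect(c("organism", "system", "matrix", "distance_class",
                     "month_index"), names(results))
  out <- dplyr::summarise(
    dplyr::group_by(results, dplyr::across(dplyr::all_of(grp))),
    mean_value = mean(.data[[value]]),
    max_value = max(.data[[value]]),
    n_sites = dplyr::n_distinct(.data$site_id),
    .groups = "drop")
  out$complete <- out$n_sites >= n_reps
  if (any(!out$complete)) {
    warning(sum(!out$complete),
            " aggregation cell(s) have fewer than ", n_reps,
            " replicate sites", call. = FALSE)
  }
  if (value == "mrq") {
    out$mean_category <- categorize_mrq(out$mean_value)
    out$max_category <- categorize_mrq(out$max_value)
  } else {
    out$mean_hazard <- out$mean_value > 1
    out$max_hazard <- out$max_value > 1
  }
  out
}
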