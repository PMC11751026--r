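# Fixture builders and independent brute-force oracles. The oracles are
# deliberately plain loops over rows, sharing no code path with the
# package's vectorised implementations.

toy_compounds <- function(ids, pclass = NULL) {
  if (is.null(pclass)) {
    pclass <- rep(c("fungicide", "herbicide", "insecticide"),
                  length.out = length(ids))
  }
  compound_table(compound_id = ids, pclass = pclass)
}

# one-sample record rows in the internal layout
toy_records <- function(compound_id, concentration, detect_status,
                        loq = 1, lod = 1 / 3, site_id = "s1",
                        system = "arable", matrix = "soil",
                        distance_class = "in_field", month_index = 0L) {
  tibble::tibble(site_id = site_id, system = system, matrix = matrix,
                 distance_class = distance_class,
                 month_index = month_index, compound_id = compound_id,
                 concentration = concentration,
                 detect_status = detect_status, loq = loq, lod = lod)
}

toy_table <- function(records, compounds = NULL) {
  if (is.null(compounds)) compounds <- toy_compounds(unique(records$compound_id))
  residue_table(records, compounds)
}

# brute-force additive mixture risk: plain loop, NOEC/AF else LC50/AF
brute_mrq <- function(records, endpoints, organism,
                      af_noec = 10, af_lc50 = 1000) {
  total <- 0
  for (i in seq_len(nrow(records))) {
    if (records$detect_status[i] == "not_detected") next
    j <- which(endpoints$compound_id == records$compound_id[i])
    if (!length(j)) next
    noec <- if (organism == "collembola") endpoints$noec_collembola[j]
            else endpoints$noec_earthworm[j]
    lc50 <- if (organism == "earthworm") endpoints$lc50_earthworm[j]
            else NA_real_
    pnec_mg <- if (!is.na(noec)) noec / af_noec
               else if (!is.na(lc50)) lc50 / af_lc50 else NA_real_
    if (is.na(pnec_mg)) next
    total <- total + records$concentration[i] / (pnec_mg * 1000)
  }
  total
}

# brute-force bee mixture hazard: sum of (contact * mec) / (ld50 / divisor)
brute_mhq <- function(records, endpoints, soil_contact = 2.23,
                      surrogate_divisor = 10) {
  total <- 0
  for (i in seq_len(nrow(records))) {
    if (records$detect_status[i] == "not_detected") next
    j <- which(endpoints$compound_id == records$compound_id[i])
    if (!length(j) || is.na(endpoints$ld50_bee[j])) next
    total <- total + (soil_contact * records$concentration[i]) /
      (endpoints$ld50_bee[j] / surrogate_divisor)
  }
  total
}

# random toy sample + endpoint pair for the oracle-equivalence check
random_toy_sample <- function(n_compounds) {
  ids <- sprintf("c%02d", seq_len(n_compounds))
  loq <- 1
  status <- sample(c("quantified", "below_loq", "not_detected"),
                   n_compounds, replace = TRUE)
  conc <- ifelse(status == "quantified", loq + stats::runif(n_compounds, 0, 200), 0)
  recs <- toy_records(ids, conc, status, loq = loq)
  ep <- endpoint_table(tibble::tibble(
    compound_id = ids,
    noec_collembola = ifelse(stats::runif(n_compounds) < 0.8,
                             stats::runif(n_compounds, 0.1, 10), NA_real_),
    noec_earthworm = ifelse(stats::runif(n_compounds) < 0.7,
                            stats::runif(n_compounds, 0.1, 10), NA_real_),
    lc50_earthworm = ifelse(stats::runif(n_compounds) < 0.5,
                            stats::runif(n_compounds, 10, 1000), NA_real_),
    ld50_bee = ifelse(stats::runif(n_compounds) < 0.9,
                      stats::runif(n_compounds, 20, 1e5), NA_real_)))
  list(records = recs, endpoints = ep)
}

# campaign with a planted vegetation count maximum in August (month 6):
# two persistent baseline compounds plus short-lived low-dose pulses
# applied in July and August
planted_peak_config <- function(seed) {
  cmp <- tibble::tibble(
    compound_id = c("base_f", "base_h", paste0("pulse_", 1:8)),
    name = c("base_f", "base_h", paste0("pulse_", 1:8)),
    pclass = c("fungicide", "herbicide", rep("fungicide", 4),
               rep("insecticide", 4)),
    dt50_months = 6, loq = 1, lod = 1 / 3)
  apps <- dplyr::bind_rows(lapply(cup_systems(), function(s) {
    tibble::tibble(system = s,
                   compound_id = c("base_f", "base_h",
                                   paste0("pulse_", 1:8)),
                   month_index = c(0L, 0L, rep(5L, 4), rep(6L, 4)),
                   dose = c(100, 100, rep(0.27, 8)))
  }))
  synthetic_config(seed = seed, compounds = cmp, applications = apps)
}
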