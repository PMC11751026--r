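# Synthetic residue campaigns with known ground truth. The generator
# reproduces the statistical structure the downstream estimators assume:
# seasonal application pulses, first-order soil dissipation, exponential
# drift with distance, vegetation interception with growth dilution and
# mowing resets, multiplicative lognormal measurement noise, and LOD/LOQ
# left-censoring. Every quantity a downstream estimator targets is stored
# as ground truth. All endpoint and application values here are synthetic:
# plausible for the compound classes, not literature values.

#' Default synthetic compound set
#'
#' Fourteen compounds (six fungicides, four herbicides, four insecticides)
#' with per-compound soil half-lives (months) and quantification limits
#' (ug/kg; LOD = LOQ / 3).
#'
#' @return Tibble with columns `compound_id`, `name`, `pclass`,
#'   `dt50_months`, `loq`, `lod`.
#' @export
default_compounds <- function() {
  x <- tibble::tribble(
    ~compound_id,          ~pclass,       ~dt50_months, ~loq,
    "fluopyram",           "fungicide",   6.0,  1.0,
    "azoxystrobin",        "fungicide",   2.0,  1.0,
    "metrafenone",         "fungicide",   2.0,  1.0,
    "dimethomorph",        "fungicide",   1.5,  1.0,
    "boscalid",            "fungicide",   4.0,  1.0,
    "difenoconazole",      "fungicide",   3.0,  0.5,
    "pendimethalin",       "herbicide",   3.0,  2.0,
    "prosulfocarb",        "herbicide",   1.0,  1.0,
    "terbuthylazine",      "herbicide",   2.0,  0.5,
    "s_metolachlor",       "herbicide",   1.5,  1.0,
    "chlorantraniliprole", "insecticide", 5.0,  0.5,
    "clothianidin",        "insecticide", 4.0,  0.2,
    "thiamethoxam",        "insecticide", 2.0,  0.2,
    "cyantraniliprole",    "insecticide", 2.0,  0.5)
  x$name <- x$compound_id
  x$lod <- x$loq / 3
  x[, c("compound_id", "name", "pclass", "dt50_months", "loq", "lod")]
}

#' Default application calendars
#'
#' One row per (system, compound, month) application pulse with the applied
#' in-field soil dose (ug/kg increment). Month indices follow the 0..12
#' grid of [month_labels()]. The qualitative pattern mirrors regional
#' practice: arable fields receive spring and autumn pulses, vegetable
#' fields repeated pulses across the season, and viticulture a
#' fungicide-heavy May-August programme.
#'
#' @return Tibble with columns `system`, `compound_id`, `month_index`,
#'   `dose`.
#' @export
default_applications <- function() {
  app <- function(system, compound_id, months, dose) {
    tibble::tibble(system = system, compound_id = compound_id,
                   month_index = as.integer(months), dose = dose)
  }
  dplyr::bind_rows(
    # arable: spring (Mar, Apr) + autumn (Sep, Oct) pulses
    app("arable", "prosulfocarb",        c(1L, 8L),  80),
    app("arable", "terbuthylazine",      c(2L),      70),
    app("arable", "pendimethalin",       c(1L, 8L), 150),
    app("arable", "azoxystrobin",        c(3L, 4L),  60),
    app("arable", "fluopyram",           c(4L),      30),
    app("arable", "chlorantraniliprole", c(4L),      15),
    app("arable", "thiamethoxam",        c(2L, 7L),   4),
    # vegetable: repeated pulses across the cropping season (Apr-Oct)
    app("vegetable", "s_metolachlor",       c(2L, 5L),      90),
    app("vegetable", "pendimethalin",       c(3L, 8L),     200),
    app("vegetable", "azoxystrobin",        c(3L, 6L, 8L),  60),
    app("vegetable", "boscalid",            c(4L, 7L),      40),
    app("vegetable", "difenoconazole",      c(5L, 8L),      25),
    app("vegetable", "fluopyram",           c(2L, 6L),      30),
    app("vegetable", "chlorantraniliprole", c(3L, 6L),      15),
    app("vegetable", "clothianidin",        c(7L),           5),
    app("vegetable", "cyantraniliprole",    c(5L, 8L),       8),
    # viticulture: fungicide-heavy May-August programme
    app("viticulture", "metrafenone",  c(3L, 5L),      50),
    app("viticulture", "dimethomorph", c(4L, 5L, 6L), 120),
    app("viticulture", "boscalid",     c(4L, 6L),      40),
    app("viticulture", "fluopyram",    c(3L, 6L),      30),
    app("viticulture", "azoxystrobin", c(5L),          60)
  )
}

#' Configure a synthetic residue campaign
#'
#' The defaults describe the emulated study design: 3 replicate sites per
#' management system, 13 monthly campaigns, 4 distance classes, the
#' compound set of [default_compounds()] applied per
#' [default_applications()], per-system drift decay rates (1/m, negative),
#' and lognormal measurement noise with coefficient of variation
#' `noise_cv`.
#'
#' Vegetation dynamics: at each application the plant compartment receives
#' `dose * vegetation_interception * vegetation_mass_ratio` (the mass ratio
#' converts a soil-referenced dose to the much smaller intercepting plant
#' biomass, giving the higher vegetation concentrations seen in the field);
#' between months the plant concentration is multiplied by
#' `vegetation_dilution` (growth dilution + wash-off), and off-field
#' vegetation is reset to zero in `mowing_months` before that month's
#' drift deposit.
#'
#' @param seed Integer seed; a fixed seed yields byte-identical campaigns.
#' @param n_sites_per_system Replicate sites per management system.
#' @param months Number of monthly campaigns (grid `0:(months-1)`).
#' @param compounds Compound table as in [default_compounds()].
#' @param applications Application calendar as in [default_applications()].
#' @param drift_decay Named numeric, per-system true drift decay `b` (1/m,
#'   < 0), applied as `exp(b * x)` to both matrices.
#' @param vegetation_interception Fraction of an application intercepted by
#'   vegetation, in `[0, 1]`.
#' @param vegetation_mass_ratio Soil-to-plant mass ratio scaling intercepted
#'   dose to plant concentration (unitless, >= 1).
#' @param vegetation_dilution Per-month multiplicative retention factor of
#'   plant residues, in `[0, 1]`.
#' @param mowing_months Integer months at which off-field vegetation is
#'   mowed (reset to zero).
#' @param noise_cv Coefficient of variation of multiplicative lognormal
#'   measurement noise (mean 1); 0 disables noise.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             n_sites_per_system = 3L,
                             months = 13L,
                             compounds = default_compounds(),
                             applications = default_applications(),
                             drift_decay = c(arable = -0.47,
                                             vegetable = -0.52,
                                             viticulture = -0.11),
                             vegetation_interception = 0.5,
                             vegetation_mass_ratio = 20,
                             vegetation_dilution = 0.25,
                             mowing_months = c(4L, 8L),
                             noise_cv = 0.3) {
  cfg <- list(seed = as.integer(seed),
              n_sites_per_system = as.integer(n_sites_per_system),
              months = as.integer(months),
              compounds = tibble::as_tibble(compounds),
              applications = tibble::as_tibble(applications),
              drift_decay = drift_decay,
              vegetation_interception = vegetation_interception,
              vegetation_mass_ratio = vegetation_mass_ratio,
              vegetation_dilution = vegetation_dilution,
              mowing_months = as.integer(mowing_months),
              noise_cv = noise_cv)
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  stopifnot(cfg$n_sites_per_system >= 1L, cfg$months >= 1L)
  cmp <- cfg$compounds
  need <- c("compound_id", "pclass", "dt50_months", "loq", "lod")
  miss <- setdiff(need, names(cmp))
  if (length(miss)) stop("compounds table missing: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!"name" %in% names(cmp)) cmp$name <- cmp$compound_id
  if (any(cmp$dt50_months <= 0)) stop("dt50 must be > 0", call. = FALSE)
  if (any(cmp$loq <= 0) || any(cmp$lod <= 0) || any(cmp$lod > cmp$loq)) {
    stop("need 0 < lod <= loq per compound", call. = FALSE)
  }
  app <- cfg$applications
  needa <- c("system", "compound_id", "month_index", "dose")
  if (length(setdiff(needa, names(app)))) {
    stop("applications table missing columns", call. = FALSE)
  }
  if (!all(app$system %in% cup_systems())) stop("invalid system in applications",
                                                call. = FALSE)
  if (!all(app$compound_id %in% cmp$compound_id)) {
    stop("application for unknown compound", call. = FALSE)
  }
  if (any(app$dose < 0)) stop("dose must be >= 0", call. = FALSE)
  systems <- unique(app$system)
  if (!all(systems %in% names(cfg$drift_decay))) {
    stop("drift_decay must name every system with applications", call. = FALSE)
  }
  if (any(cfg$drift_decay >= 0)) stop("drift_decay must be < 0", call. = FALSE)
  if (cfg$vegetation_interception < 0 || cfg$vegetation_interception > 1) {
    stop("vegetation_interception must be in [0, 1]", call. = FALSE)
  }
  if (cfg$vegetation_dilution < 0 || cfg$vegetation_dilution > 1) {
    stop("vegetation_dilution must be in [0, 1]", call. = FALSE)
  }
  if (cfg$vegetation_mass_ratio < 1) stop("vegetation_mass_ratio must be >= 1",
                                          call. = FALSE)
  if (cfg$noise_cv < 0) stop("noise_cv must be >= 0", call. = FALSE)
  cfg$compounds <- cmp
  structure(cfg, class = "synthetic_config")
}

# noiseless in-field / off-field concentration surfaces for one system
truth_surfaces <- function(cfg, system) {
  months <- 0:(cfg$months - 1L)
  b <- cfg$drift_decay[[system]]
  xs <- map_distance(cup_distance_classes())
  apps <- cfg$applications[cfg$applications$system == system, ]
  out <- vector("list", nrow(cfg$compounds))
  for (j in seq_len(nrow(cfg$compounds))) {
    cmp <- cfg$compounds[j, ]
    aj <- apps[apps$compound_id == cmp$compound_id, ]
    soil_in <- numeric(length(months))
    veg_dep <- numeric(length(months))       # per-month deposit on plants
    for (k in seq_len(nrow(aj))) {
      m0 <- aj$month_index[k]
      later <- months >= m0
      soil_in[later] <- soil_in[later] +
        aj$dose[k] * 0.5 ^ ((months[later] - m0) / cmp$dt50_months)
      veg_dep[months == m0] <- veg_dep[months == m0] +
        aj$dose[k] * cfg$vegetation_interception * cfg$vegetation_mass_ratio
    }
    per_dist <- lapply(seq_along(xs), function(i) {
      drift <- exp(b * xs[i])
      veg <- numeric(length(months))
      for (m in seq_along(months)) {
        carry <- if (m == 1L) 0 else veg[m - 1L] * cfg$vegetation_dilution
        if (xs[i] > 0 && months[m] %in% cfg$mowing_months) carry <- 0
        veg[m] <- carry + veg_dep[m] * drift
      }
      tibble::tibble(system = system,
                     distance_class = names(xs)[i],
                     month_index = months,
                     compound_id = cmp$compound_id,
                     soil = soil_in * drift,
                     vegetation = veg)
    })
    out[[j]] <- dplyr::bind_rows(per_dist)
  }
  dplyr::bind_rows(out)
}

#' Generate a synthetic residue campaign
#'
#' Produces a validated [residue_table()] together with the ground truth
#' behind it. In-field soil concentrations follow the sum of application
#' pulses decayed first-order (half-life `dt50_months`); off-field
#' concentrations at distance `x` equal the in-field level times
#' `exp(b_true * x)`; vegetation follows interception with per-month
#' dilution and mowing resets (see [synthetic_config()]). Observed
#' concentrations are the noiseless values times mean-1 lognormal noise,
#' then left-censored: below LOD the record is `not_detected`, in
#' `[LOD, LOQ)` it is `below_loq` with concentration 0, at or above LOQ it
#' is `quantified`. Output is deterministic under a fixed seed.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `table` (a [residue_table()]) and `truth`
#'   (class `ground_truth`: per-record noiseless concentrations, per-system
#'   `b_true`, in-field concentration surfaces and planted peak months).
#' @export
generate_campaign <- function(config) {
  config <- validate_synthetic_config(unclass(config))
  set.seed(config$seed)
  systems <- sort(unique(config$applications$system))

  truth_long <- dplyr::bind_rows(lapply(systems, truth_surfaces, cfg = config))
  truth_long <- tidyr::pivot_longer(truth_long, c("soil", "vegetation"),
                                    names_to = "matrix",
                                    values_to = "conc_true")

  sites <- dplyr::bind_rows(lapply(systems, function(s) {
    tibble::tibble(system = s,
                   site_id = sprintf("%s_%d", s,
                                     seq_len(config$n_sites_per_system)))
  }))
  grid <- dplyr::inner_join(sites, truth_long, by = "system",
                            relationship = "many-to-many")
  grid <- dplyr::arrange(grid, .data$system, .data$site_id, .data$matrix,
                         .data$distance_class, .data$month_index,
                         .data$compound_id)

  cv <- config$noise_cv
  eps <- if (cv > 0) {
    sdlog <- sqrt(log1p(cv^2))
    rlnorm(nrow(grid), meanlog = -sdlog^2 / 2, sdlog = sdlog)
  } else rep(1, nrow(grid))
  obs <- grid$conc_true * eps

  cmp <- config$compounds
  loq <- cmp$loq[match(grid$compound_id, cmp$compound_id)]
  lod <- cmp$lod[match(grid$compound_id, cmp$compound_id)]
  status <- ifelse(obs >= loq, "quantified",
                   ifelse(obs >= lod, "below_loq", "not_detected"))
  records <- tibble::tibble(
    site_id = grid$site_id, system = grid$system, matrix = grid$matrix,
    distance_class = grid$distance_class, month_index = grid$month_index,
    compound_id = grid$compound_id,
    concentration = ifelse(status == "quantified", obs, 0),
    detect_status = status, loq = loq, lod = lod)

  table <- residue_table(records,
                         cmp[, c("compound_id", "name", "pclass")])

  infield <- truth_long[truth_long$distance_class == "in_field", ]
  # planted peak months: argmax of the noiseless in-field detected-CUP count
  counts <- dplyr::summarise(
    dplyr::group_by(
      dplyr::mutate(infield,
                    lod = cmp$lod[match(.data$compound_id, cmp$compound_id)]),
      .data$system, .data$matrix, .data$month_index),
    n_cups = sum(.data$conc_true >= .data$lod), .groups = "drop_last")
  peaks <- dplyr::ungroup(
    dplyr::filter(counts, .data$n_cups == max(.data$n_cups)))
  truth <- structure(
    list(noiseless = grid,
         b_true = config$drift_decay[systems],
         infield = infield,
         infield_counts = dplyr::ungroup(counts),
         peak_months = peaks[, c("system", "matrix", "month_index", "n_cups")],
         config = config),
    class = "ground_truth")
  list(table = table, truth = truth)
}

#' Ground-truth reference values for downstream estimators
#'
#' @param estimator One of `"distance_decay"` (per-system true drift decay
#'   `b_true`), `"peaks"` (planted in-field peak months per system and
#'   matrix), or `"mrq"` (per-sample noiseless mixture risk quotient,
#'   computed by a direct brute-force sum over compounds; requires
#'   `endpoints` and `organism`).
#' @param truth A `ground_truth` object from [generate_campaign()].
#' @param endpoints,organism Used by `"mrq"` only.
#' @return The reference quantity for the named estimator.
#' @export
truth_for <- function(estimator, truth,
                      endpoints = NULL,
                      organism = c("collembola", "earthworm")) {
  stopifnot(inherits(truth, "ground_truth"))
  switch(
    estimator,
    distance_decay = truth$b_true,
    peaks = truth$peak_months,
    mrq = {
      if (is.null(endpoints)) stop("mrq truth needs an endpoint table",
                                   call. = FALSE)
      organism <- match.arg(organism)
      nl <- truth$noiseless
      cmp <- truth$config$compounds
      loq <- cmp$loq[match(nl$compound_id, cmp$compound_id)]
      mec <- ifelse(nl$conc_true >= loq, nl$conc_true, 0)   # censored truth
      pn <- pnec(endpoints, organism)
      pnec_ug <- pn$pnec_mg_kg[match(nl$compound_id, pn$compound_id)] * 1000
      rq <- mec / pnec_ug
      rq[is.na(rq)] <- 0                                    # no endpoint
      out <- tibble::tibble(site_id = nl$site_id, system = nl$system,
                            matrix = nl$matrix,
                            distance_class = nl$distance_class,
                            month_index = nl$month_index, rq = rq)
      dplyr::summarise(
        dplyr::group_by(out, .data$site_id, .data$system, .data$matrix,
                        .data$distance_class, .data$month_index),
        mrq_true = sum(.data$rq), .groups = "drop")
    },
    stop("unknown estimator: ", estimator, call. = FALSE))
}

#' Synthetic ecotoxicological endpoints for the default compound set
#'
#' Deterministic endpoint values for the compounds of
#' [default_compounds()], chosen to be plausible for each pesticide class
#' (insecticides with low bee LD50s and low collembola NOECs, fungicides
#' and herbicides with soil endpoints in the mg/kg range). These are
#' synthetic stand-ins, not literature values: one insecticide lacks a
#' collembola NOEC and two carry only an earthworm LC50, so coverage
#' bookkeeping and the LC50 fallback are exercised.
#'
#' @return An `endpoint_table`.
#' @export
synthetic_endpoints <- function() {
  x <- tibble::tribble(
    ~compound_id,          ~noec_collembola, ~noec_earthworm, ~lc50_earthworm, ~ld50_bee,
    "fluopyram",           1.0,   1.2,   NA,    1e5,
    "azoxystrobin",        4.0,   0.35,  NA,    2e5,
    "metrafenone",         10,    10,    NA,    1e5,
    "dimethomorph",        5,     6,     NA,    1e5,
    "boscalid",            2.5,   0.5,   NA,    1e5,
    "difenoconazole",      1.5,   0.15,  NA,    1e5,
    "pendimethalin",       10,    3,     NA,    5e4,
    "prosulfocarb",        8,     2,     NA,    4e4,
    "terbuthylazine",      2,     0.3,   NA,    2e4,
    "s_metolachlor",       5,     2,     NA,    5e4,
    "chlorantraniliprole", 0.4,   NA,    1000,  9000,
    "clothianidin",        0.3,   1.0,   NA,    44,
    "thiamethoxam",        0.2,   NA,    500,   24,
    "cyantraniliprole",    NA,    0.1,   NA,    93)
  x$source <- "synthetic plausible values"
  endpoint_table(x)
}
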