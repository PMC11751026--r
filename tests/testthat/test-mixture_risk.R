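ep_two <- function() {
  endpoint_table(tibble::tibble(
    compound_id = c("A", "B"),
    noec_collembola = c(1, 1),      # PNEC 0.1 mg/kg = 100 ug/kg
    noec_earthworm = c(2, NA),
    lc50_earthworm = c(NA, 1000),
    ld50_bee = c(1000, 500)))
}

test_that("PNEC derivation prefers NOEC/10 and falls back to LC50/1000", {
  ep <- endpoint_table(tibble::tibble(
    compound_id = c("n", "l", "both", "none"),
    noec_earthworm = c(10, NA, 5, NA),
    lc50_earthworm = c(NA, 1000, 1000, NA)))
  p <- pnec(ep, "earthworm")
  expect_equal(p$pnec_mg_kg[p$compound_id == "n"], 1)
  expect_equal(p$pnec_mg_kg[p$compound_id == "l"], 1)
  expect_equal(p$pnec_mg_kg[p$compound_id == "both"], 0.5)
  expect_equal(p$endpoint_kind[p$compound_id == "both"], "NOEC")
  expect_true(is.na(p$pnec_mg_kg[p$compound_id == "none"]))
  # collembola endpoints are NOEC-only: an earthworm LC50 never leaks in
  pc <- pnec(ep, "collembola")
  expect_true(all(is.na(pc$pnec_mg_kg)))
})

test_that("sample MRQ matches hand arithmetic and reports attribution", {
  recs <- toy_records(c("A", "B"), c(100, 50), "quantified")
  r <- sample_mrq(recs, ep_two(), "collembola")
  expect_equal(unname(r$rq), c(1.0, 0.5))
  expect_equal(r$mrq, 1.5)
  expect_equal(r$rq_max, 1.0)
  expect_equal(r$rq_max_compound, "A")
  expect_equal(r$frac_rq_max, 2 / 3)
  expect_equal(r$coverage, 1)
  expect_equal(r$category, "very_high")
})

test_that("empty samples and missing endpoints degrade gracefully", {
  empty <- toy_records("A", 0, "not_detected")
  r <- sample_mrq(empty, ep_two(), "collembola")
  expect_equal(r$mrq, 0)
  expect_equal(r$category, "negligible")
  expect_equal(r$frac_rq_max, 0)
  # below-LOQ detection contributes 0 but appears in coverage's denominator
  ep3 <- endpoint_table(tibble::tibble(compound_id = c("A", "B", "C"),
                                       noec_collembola = c(1, 1, NA)))
  recs <- toy_records(c("A", "B", "C"), c(100, 0, 50),
                      c("quantified", "below_loq", "quantified"))
  r3 <- sample_mrq(recs, ep3, "collembola")
  expect_equal(r3$mrq, 1.0)            # C has no endpoint, B censored to 0
  expect_equal(r3$coverage, 2 / 3)
  expect_equal(r3$n_detected, 3L)
})

test_that("MRQ scales linearly in MEC and is additive over partitions", {
  set.seed(21)
  recs <- toy_records(sprintf("c%02d", 1:10),
                      stats::runif(10, 1, 300), "quantified")
  ep <- random_toy_sample(10)$endpoints
  recs$compound_id <- ep$compound_id
  r1 <- sample_mrq(recs, ep, "earthworm")
  doubled <- recs
  doubled$concentration <- doubled$concentration * 2
  expect_equal(sample_mrq(doubled, ep, "earthworm")$mrq, 2 * r1$mrq,
               tolerance = 1e-12)
  # partition additivity, exact
  part <- sample_mrq(recs[1:4, ], ep, "earthworm")$mrq +
    sample_mrq(recs[5:10, ], ep, "earthworm")$mrq
  expect_identical(part, r1$mrq)
  # removing the top compound removes exactly rq_max
  drop <- recs[recs$compound_id != r1$rq_max_compound, ]
  expect_equal(sample_mrq(drop, ep, "earthworm")$mrq, r1$mrq - r1$rq_max,
               tolerance = 1e-12)
})

test_that("risk categories use left-closed bands with high at exactly 1", {
  expect_equal(categorize_mrq(c(0, 0.005, 0.01, 0.05, 0.1, 0.5, 1, 1.5)),
               c("negligible", "negligible", "low", "low", "medium",
                 "medium", "high", "very_high"))
  expect_error(categorize_mrq(-0.1), ">= 0")
})

test_that("bee hazard quotient follows the contact scenario arithmetic", {
  expect_equal(bee_hq(100, 1000), 2.23)          # (2.23 * 100) / (1000/10)
  expect_equal(bee_hq(0, 1000), 0)
  expect_equal(bee_hq(100, 1000, soil_contact = 1, surrogate_divisor = 1),
               0.1)
  expect_error(bee_hq(10, 0), "> 0")
  expect_error(bee_hq(-1, 100), ">= 0")
})

test_that("sample MHQ sums hazard quotients with a strict threshold", {
  # two compounds, each HQ 0.6 -> hazard; single HQ exactly 1 -> none
  ep <- endpoint_table(tibble::tibble(compound_id = c("A", "B"),
                                      ld50_bee = c(2.23 * 1000, 2.23 * 1000)))
  recs <- toy_records(c("A", "B"), c(60, 60), "quantified")
  r <- sample_mhq(recs, ep)
  expect_equal(r$mhq, 1.2, tolerance = 1e-12)
  expect_true(r$hazard)
  one <- sample_mhq(toy_records("A", 100, "quantified"), ep)
  expect_equal(one$mhq, 1, tolerance = 1e-12)
  expect_false(one$hazard)
})

test_that("aggregation over replicate sites reports mean, max and completeness", {
  recs <- dplyr::bind_rows(lapply(1:3, function(i)
    toy_records("A", c(20, 40, 60)[i], "quantified",
                site_id = sprintf("site%d", i))))
  tab <- toy_table(recs)
  rt <- risk_table(tab, ep_two(), "collembola")
  agg <- aggregate_risk(rt, "mrq")
  expect_equal(agg$mean_value, 0.4)
  expect_equal(agg$max_value, 0.6)
  expect_true(agg$complete)
  expect_equal(agg$mean_category, "medium")
  # missing replicate is flagged with a warning, mean over the remaining 2
  rt2 <- rt[rt$site_id != "site3", ]
  expect_warning(agg2 <- aggregate_risk(rt2, "mrq"), "fewer than 3")
  expect_equal(agg2$mean_value, 0.3)
  expect_false(agg2$complete)
  # composed categorisation of an aggregated mean above 1
  expect_equal(categorize_mrq(1.1), "very_high")
})

test_that("noiseless campaign MRQ matches the ground-truth closed form", {
  cfg <- synthetic_config(seed = 1, noise_cv = 0)
  sim <- generate_campaign(cfg)
  ep <- synthetic_endpoints()
  for (org in c("collembola", "earthworm")) {
    rt <- risk_table(sim$table, ep, org, matrix = "soil")
    tr <- truth_for("mrq", sim$truth, endpoints = ep, organism = org)
    tr <- tr[tr$matrix == "soil", ]
    m <- dplyr::inner_join(rt, tr,
                           by = c("site_id", "system", "matrix",
                                  "distance_class", "month_index"))
    expect_equal(nrow(m), nrow(rt))
    expect_lt(max(abs(m$mrq - m$mrq_true)), 1e-12)
  }
})
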