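make_four_sample_table <- function() {
  # 4 soil samples over compounds A/B/C; A quantified in s1+s2 (10, 20),
  # detected below LOQ in s3, absent in s4
  recs <- dplyr::bind_rows(
    toy_records(c("A", "B"), c(10, 5), "quantified", site_id = "s1"),
    toy_records(c("A", "B"), c(20, 0), c("quantified", "below_loq"),
                site_id = "s2"),
    toy_records(c("A", "C"), c(0, 2), c("below_loq", "quantified"),
                site_id = "s3"),
    toy_records("B", 3, "quantified", site_id = "s4"))
  toy_table(recs, toy_compounds(c("A", "B", "C"),
                                c("fungicide", "herbicide", "insecticide")))
}

test_that("sample summaries count below-LOQ detections but exclude them from totals", {
  recs <- toy_records(c("A", "B", "C", "D"), c(10, 5, 0, 0),
                      c("quantified", "quantified", "below_loq",
                        "not_detected"))
  s <- summarize_samples(toy_table(recs))
  expect_equal(s$n_cups_detected, 3L)
  expect_equal(s$n_quantified, 2L)
  expect_equal(s$total_concentration, 15)

  empty <- summarize_samples(toy_table(
    toy_records(c("A", "B"), c(0, 0), "not_detected")))
  expect_equal(empty$n_cups_detected, 0L)
  expect_equal(empty$total_concentration, 0)
})

test_that("detection frequency counts detected samples per compound", {
  tab <- make_four_sample_table()
  f <- detection_frequency(tab, "soil")
  expect_equal(f$detection_frequency[f$compound_id == "A"], 100 * 3 / 4)
  expect_equal(f$detection_frequency[f$compound_id == "C"], 25)
  # compound in the table but never recorded -> 0%
  tab2 <- residue_table(tab$records,
                        toy_compounds(c("A", "B", "C", "Z"),
                                      c("fungicide", "herbicide",
                                        "insecticide", "fungicide")))
  f2 <- detection_frequency(tab2, "soil")
  expect_equal(f2$detection_frequency[f2$compound_id == "Z"], 0)
  expect_error(detection_frequency(tab, "vegetation"), "no samples")
})

test_that("detection frequency toy case: 2 of 3 samples is 66.67%", {
  recs <- dplyr::bind_rows(
    toy_records("A", 5, "quantified", site_id = "s1"),
    toy_records("A", 0, "below_loq", site_id = "s2"),
    toy_records("A", 0, "not_detected", site_id = "s3"))
  f <- detection_frequency(toy_table(recs), "soil")
  expect_equal(f$detection_frequency, 100 * 2 / 3, tolerance = 1e-12)
})

test_that("concentration statistics report both mean variants and the max", {
  tab <- make_four_sample_table()
  cs <- concentration_stats(tab, "soil")
  a <- cs[cs$compound_id == "A", ]
  expect_equal(a$mean_quantified, 15)   # over {10, 20}
  expect_equal(a$mean_all, 30 / 4)      # over all 4 soil samples
  expect_equal(a$max_concentration, 20)
  # single quantified value: all statistics collapse onto it
  cC <- cs[cs$compound_id == "C", ]
  expect_equal(cC$mean_quantified, 2)
  expect_equal(cC$max_concentration, 2)
  # all-below-LOQ compound: absent from stats, still has frequency
  recs <- toy_records("A", 0, "below_loq")
  tb <- toy_table(recs)
  expect_equal(nrow(concentration_stats(tb, "soil")), 0L)
  expect_gt(detection_frequency(tb, "soil")$detection_frequency, 0)
})

test_that("mean over all samples never exceeds mean over quantified", {
  sim <- generate_campaign(synthetic_config(seed = 9))
  for (m in c("soil", "vegetation")) {
    cs <- concentration_stats(sim$table, m)
    expect_true(all(cs$mean_all <= cs$mean_quantified + 1e-12))
  }
})

test_that("mixture enumeration is order-independent and counts insecticide mixtures", {
  recs <- dplyr::bind_rows(
    toy_records(c("A", "B"), c(5, 6), "quantified", site_id = "s1"),
    toy_records(c("B", "A"), c(7, 8), "quantified", site_id = "s2"),
    toy_records("A", 9, "quantified", site_id = "s3"))
  mix <- enumerate_mixtures(toy_table(recs, toy_compounds(
    c("A", "B"), c("fungicide", "herbicide"))), "soil")
  expect_equal(mix$n_unique, 2L)
  expect_equal(mix$most_frequent$mixture_key, "A|B")
  expect_equal(mix$most_frequent$n_samples, 2L)
  expect_equal(mix$n_with_insecticide, 0L)
})

test_that("mixture enumeration matches exhaustive hand enumeration on a toy table", {
  # 5 samples over 3 compounds (C is the insecticide):
  # s1 {A,B}, s2 {A,B}, s3 {A,B,C}, s4 {C}, s5 {} (empty)
  recs <- dplyr::bind_rows(
    toy_records(c("A", "B"), c(5, 6), "quantified", site_id = "s1"),
    toy_records(c("A", "B"), c(1, 0), c("quantified", "below_loq"),
                site_id = "s2"),
    toy_records(c("A", "B", "C"), c(2, 3, 4), "quantified", site_id = "s3"),
    toy_records("C", 8, "quantified", site_id = "s4"),
    toy_records("A", 0, "not_detected", site_id = "s5"))
  mix <- enumerate_mixtures(toy_table(recs, toy_compounds(
    c("A", "B", "C"), c("fungicide", "herbicide", "insecticide"))), "soil")
  expect_equal(mix$n_unique, 3L)
  expect_equal(mix$n_with_insecticide, 2L)    # {A,B,C} and {C}
  expect_equal(mix$n_empty_samples, 1L)
  counts <- setNames(mix$counts$n_samples, mix$counts$mixture_key)
  expect_equal(counts[["A|B"]], 2L)
  expect_equal(counts[["A|B|C"]], 1L)
  expect_equal(counts[["C"]], 1L)
  # mixture counts partition the non-empty samples
  expect_equal(sum(mix$counts$n_samples) + mix$n_empty_samples, 5L)
})

test_that("summaries are invariant under record order permutation", {
  sim <- generate_campaign(synthetic_config(seed = 4))
  shuffled <- sim$table
  set.seed(99)
  shuffled$records <- shuffled$records[sample(nrow(shuffled$records)), ]
  f1 <- detection_frequency(sim$table, "soil")
  f2 <- detection_frequency(shuffled, "soil")
  expect_equal(f1, f2)
  expect_equal(enumerate_mixtures(sim$table, "soil")$counts,
               enumerate_mixtures(shuffled, "soil")$counts)
})

test_that("noiseless campaign counts equal closed-form expectations", {
  cfg <- synthetic_config(seed = 1, noise_cv = 0)
  sim <- generate_campaign(cfg)
  s <- summarize_samples(sim$table)
  # expected per-month in-field soil count from the config, independently:
  # compounds whose summed decayed pulses reach the LOD
  cmp <- cfg$compounds
  apps <- cfg$applications
  for (sys in c("arable", "viticulture")) {
    for (m in c(0L, 6L, 12L)) {
      expected <- 0L
      for (j in seq_len(nrow(cmp))) {
        aj <- apps[apps$system == sys & apps$compound_id == cmp$compound_id[j], ]
        if (!nrow(aj)) next
        conc <- sum(aj$dose[aj$month_index <= m] *
                      0.5^((m - aj$month_index[aj$month_index <= m]) /
                             cmp$dt50_months[j]))
        if (conc >= cmp$lod[j]) expected <- expected + 1L
      }
      got <- s$n_cups_detected[s$system == sys & s$matrix == "soil" &
                                 s$distance_class == "in_field" &
                                 s$month_index == m]
      expect_true(all(got == expected))
    }
  }
})
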