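linear_series <- function(n = 13, a = 2, b = 1) {
  tibble::tibble(month_index = 0:(n - 1), value = a * (0:(n - 1)) + b)
}

test_that("loess reproduces polynomial and constant series on the grid", {
  ser <- linear_series()
  for (sp in c(0.4, 0.75, 1)) {
    sm <- fit_loess(ser, span = sp)
    expect_equal(sm$fitted, ser$value, tolerance = 1e-8)
  }
  const <- tibble::tibble(month_index = 0:12, value = rep(3.5, 13))
  expect_equal(fit_loess(const, span = 0.75)$fitted, rep(3.5, 13),
               tolerance = 1e-8)
  expect_error(fit_loess(ser[1:3, ], span = 0.75), "at least 4")
  expect_error(fit_loess(ser, span = 0.1), "window")
})

test_that("smoothing a noisy sinusoid beats the raw values against truth", {
  set.seed(101)
  truth <- sin(2 * pi * (0:12) / 12)
  noisy <- truth + stats::rnorm(13, sd = 0.3)
  ser <- tibble::tibble(month_index = 0:12, value = noisy)
  sm <- fit_loess(ser, span = 0.6)
  expect_lt(mean((sm$fitted - truth)^2), mean((noisy - truth)^2))
})

test_that("leave-one-out span selection breaks ties upward and skips infeasible spans", {
  ser <- linear_series()
  # linear data: every span predicts perfectly -> tie -> largest wins
  expect_equal(as.numeric(select_span_cv(ser, c(0.4, 0.6, 1.0))), 1.0)
  # an infeasible window (too few points) is dropped, not an error
  expect_equal(as.numeric(select_span_cv(ser, c(0.05, 0.8))), 0.8)
  expect_error(select_span_cv(ser, c(0.05, 0.08)), "no feasible")
  expect_error(select_span_cv(ser, 0.5), "two candidate")
})

test_that("selected span scores match an independent leave-one-out loop", {
  set.seed(7)
  ser <- tibble::tibble(month_index = 0:12,
                        value = sin(2 * pi * (0:12) / 12) +
                          stats::rnorm(13, sd = 0.2))
  chosen <- select_span_cv(ser, c(0.5, 0.8))
  cv <- attr(chosen, "cv")
  # recompute one candidate by hand
  hand <- mean(vapply(1:13, function(i) {
    fit <- stats::loess(value ~ month_index, data = ser[-i, ], span = 0.8,
                        degree = 2,
                        control = stats::loess.control(surface = "direct"))
    (stats::predict(fit, newdata = ser[i, ]) - ser$value[i])^2
  }, numeric(1)))
  expect_equal(cv$cv_score[cv$span == 0.8], hand, tolerance = 1e-10)
  expect_equal(as.numeric(chosen), cv$span[which.min(cv$cv_score)])
})

test_that("linear detrending returns OLS residuals", {
  ser <- linear_series()
  d <- detrend_linear(ser)
  expect_equal(d$value, rep(0, 13), tolerance = 1e-10)
  # residuals sum to zero, largest at a planted outlier
  ser2 <- tibble::tibble(month_index = 0:4, value = c(0, 1, 2, 10, 4))
  d2 <- detrend_linear(ser2)
  expect_lt(abs(sum(d2$value)), 1e-9)
  expect_equal(which.max(abs(d2$value)), 4L)
  expect_error(detrend_linear(ser[1:2, ]), "at least 3")
  expect_error(detrend_linear(tibble::tibble(month_index = c(1, 1, 1),
                                             value = 1:3)), "degenerate")
})

test_that("delta-threshold peak detection follows the hand-traced runs", {
  pk <- detect_peaks(c(0, 1, 0), delta = 0.3)
  expect_equal(nrow(pk), 1L)
  expect_equal(pk$position, 1)
  expect_equal(pk$value, 1)
  expect_equal(pk$kind, "maximum")

  expect_equal(nrow(detect_peaks(rep(2, 10), delta = 0.3)), 0L)
  expect_equal(nrow(detect_peaks(numeric(0), delta = 0.3)), 0L)

  # the 0.8 dip is within delta of the running maximum, so only the 1.7
  # summit is emitted; the trailing minimum candidate stays pending
  pk2 <- detect_peaks(c(0, 1, 0.8, 1.7, 0.2), delta = 0.3)
  expect_equal(pk2$position, 3)
  expect_equal(pk2$value, 1.7)
  expect_equal(pk2$kind, "maximum")

  expect_error(detect_peaks(c(0, 1), delta = 0), "delta")
})

test_that("peak kinds alternate and positions are shift-invariant", {
  set.seed(12)
  for (rep in 1:20) {
    v <- stats::rnorm(30)
    pk <- detect_peaks(v, delta = 0.5)
    if (nrow(pk) > 1) {
      expect_true(all(pk$kind[-1] != pk$kind[-nrow(pk)]))
    }
    shifted <- detect_peaks(v + 17.3, delta = 0.5)
    expect_equal(shifted$position, pk$position)
    expect_equal(shifted$kind, pk$kind)
  }
})

test_that("probability normalisation floors, rescales and sums to one", {
  expect_equal(to_probability(c(1, 1, 2)), c(0.25, 0.25, 0.5))
  p <- to_probability(c(1, -0.01, 3), epsilon = 1e-6)
  expect_equal(p[2], 1e-6 / (4 + 1e-6), tolerance = 1e-12)
  expect_error(to_probability(c(-1, -2)), "<= 0")
  set.seed(3)
  for (i in 1:50) {
    p <- to_probability(stats::rnorm(13), epsilon = 1e-6)
    expect_lt(abs(sum(p) - 1), 1e-12)
    expect_true(all(p > 0))
  }
})

test_that("KL divergence matches its definition and is a divergence", {
  p <- c(0.5, 0.5)
  expect_equal(kl_divergence(p, p), 0)
  expect_equal(kl_divergence(p, c(0.25, 0.75)),
               0.5 * log2(0.5 / 0.25) + 0.5 * log2(0.5 / 0.75),
               tolerance = 1e-12)
  expect_error(kl_divergence(p, c(0.2, 0.3, 0.5)), "different grids")
  expect_error(kl_divergence(c(0.7, 0.2), c(0.5, 0.5)), "sum to 1")
})

test_that("identical annual courses give zero divergence across systems", {
  # same calendar in every system, noise off -> identical in-field series
  cmp <- default_compounds()
  apps <- dplyr::bind_rows(lapply(cup_systems(), function(s) {
    a <- default_applications()
    a <- a[a$system == "arable", ]
    a$system <- s
    a
  }))
  cfg <- synthetic_config(seed = 1, compounds = cmp, applications = apps,
                          noise_cv = 0,
                          drift_decay = c(arable = -0.4, vegetable = -0.4,
                                          viticulture = -0.4))
  sim <- generate_campaign(cfg)
  k <- compare_systems(sim$table, "soil", span = 0.75)
  expect_true(all(abs(k) < 1e-6))
  expect_equal(unname(diag(k)), rep(0, 3))
})
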