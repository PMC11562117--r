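test_that("noiseless series recover their generating parameters", {
  t <- seq(0, 48, by = 6)
  fit <- fit_d50(t, alsfrs_sigmoid(t, 30, 6))
  expect_s3_class(fit, "d50_fit")
  expect_equal(fit$d50, 30, tolerance = 1e-4)
  expect_equal(fit$dx, 6, tolerance = 1e-4)
  expect_lt(fit$rss, 1e-10)
  expect_true(fit$converged)
  expect_identical(fit$n_obs, length(t))
})

test_that("scaling observation times by k scales d50 and dx by k", {
  t <- seq(3, 45, by = 7)
  s <- alsfrs_sigmoid(t, 28, 5)
  base <- fit_d50(t, s)
  for (k in c(0.5, 2, 3.5)) {
    scaled <- fit_d50(t * k, s)
    expect_equal(scaled$d50, k * base$d50, tolerance = 1e-3)
    expect_equal(scaled$dx, k * base$dx, tolerance = 1e-3)
  }
})

test_that("fit rejects invalid series and honours min_obs", {
  expect_error(fit_d50(c(1, 2), c(40, 30), min_obs = 3), "at least 3")
  expect_error(fit_d50(c(5, 3), c(40, 30)), "strictly increasing")
  expect_error(fit_d50(c(-1, 3), c(40, 30)), ">= 0")
  expect_error(fit_d50(c(1, 3), c(40, 50)), "\\[0, 48\\]")
  expect_error(fit_d50(c(1, 3), c(40)), "lengths differ")
  # two observations plus the anchor are enough to identify both parameters
  fit <- fit_d50(c(24, 36), alsfrs_sigmoid(c(24, 36), 30, 6))
  expect_true(is.finite(fit$d50))
})

test_that("anchoring is applied by default and can be disabled", {
  # a flat late-plateau series is poorly identified without the anchor
  t <- c(40, 44, 48)
  s <- alsfrs_sigmoid(t, 20, 4)
  with_anchor <- fit_d50(t, s)
  without <- fit_d50(t, s, anchor = FALSE, min_obs = 3)
  expect_true(with_anchor$anchored)
  expect_false(without$anchored)
  # anchored fit must still explain the real observations
  expect_lt(sum((alsfrs_sigmoid(t, with_anchor$d50, with_anchor$dx) - s)^2),
            1)
})

test_that("noisy-cohort parameter recovery beats the grid-search oracle", {
  set.seed(71)
  times <- seq(6, 48, length.out = 5)
  d50_hat <- replicate(60, {
    ser <- make_series(30, 6, times, noise_sd = 2)
    fit_d50(ser$t, ser$score)$d50
  })
  expect_lt(abs(mean(d50_hat) - 30) / 30, 0.05)
  expect_lt(median(abs(d50_hat - 30)) / 30, 0.10)
  # optimizer RSS never worse than a dense grid search on the same objective
  for (i in 1:5) {
    ser <- make_series(30, 6, times, noise_sd = 2)
    fit <- fit_d50(ser$t, ser$score, anchor = FALSE)
    oracle <- oracle_grid_d50(ser$t, ser$score,
                              seq(10, 60, by = 0.1), seq(1, 20, by = 0.1))
    expect_lte(fit$rss, oracle$rss + 1e-8)
  }
})

test_that("rd50_at implements t / (2 d50) and rejects bad input", {
  fit <- fit_d50(seq(0, 48, 6), alsfrs_sigmoid(seq(0, 48, 6), 30, 6))
  expect_equal(rd50_at(fit, fit$d50), 0.5)
  expect_equal(rd50_at(fit, 0), 0)
  expect_equal(rd50_at(30, 15), 0.25)
  expect_error(rd50_at(fit, -1), ">= 0")
  expect_error(rd50_at(-5, 10), "positive")
  # linear in t, strictly decreasing in d50 for fixed t > 0
  t <- c(1, 5, 12)
  expect_equal(rd50_at(30, 3 * t), 3 * rd50_at(30, t))
  expect_true(all(diff(rd50_at(c(10, 20, 40), 12)) < 0))
})

test_that("phase labels partition [0, Inf) with half-open boundaries", {
  expect_equal(as.character(classify_phase(c(0.20, 0.25, 0.55))),
               c("I", "II", "III_IV"))
  expect_equal(as.character(classify_phase(0.50)), "III_IV")
  expect_error(classify_phase(-0.1), ">= 0")
  set.seed(4)
  x <- c(0, 0.25, 0.5, runif(200, 0, 1.5))
  ph <- classify_phase(x)
  expect_false(anyNA(ph))
  expect_identical(ph == "I", x < 0.25)
  expect_identical(ph == "II", x >= 0.25 & x < 0.50)
  expect_identical(ph == "III_IV", x >= 0.50)
})

test_that("aggressiveness splits at D50 = 30 with configurable boundary", {
  expect_equal(as.character(classify_aggressiveness(c(31, 20, 30))),
               c("LA", "HA", "HA"))
  expect_equal(as.character(classify_aggressiveness(30, boundary = "LA")),
               "LA")
  expect_error(classify_aggressiveness(0), "positive")
})

test_that("cohort fitting returns the per-patient record schema", {
  coh <- simulate_cohort(n = 12, seed = 5)
  rec <- fit_d50_cohort(coh$scores, coh$patients)
  expect_s3_class(rec, "tbl_df")
  expect_identical(nrow(rec), 12L)
  expect_true(all(c("patient_id", "d50", "dx", "rss", "converged",
                    "rd50_at_mri", "phase", "aggressiveness") %in%
                    names(rec)))
  # derived fields are internally consistent
  expect_equal(rec$rd50_at_mri, rec$t_mri_months / (2 * rec$d50))
  expect_identical(rec$phase, classify_phase(rec$rd50_at_mri))
  expect_identical(rec$aggressiveness, classify_aggressiveness(rec$d50))
  expect_true(all(rec$rss >= 0))
})

test_that("tidy and glance methods summarise a fit", {
  fit <- fit_d50(seq(0, 48, 6), alsfrs_sigmoid(seq(0, 48, 6), 30, 6))
  td <- tidy(fit)
  expect_identical(td$term, c("d50", "dx"))
  gl <- glance(fit)
  expect_identical(names(gl), c("d50", "dx", "rss", "n_obs", "converged"))
})
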