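make_records <- function(n_g1 = 6, n_g2 = 6, seed = 20) {
  set.seed(seed)
  n <- n_g1 + n_g2
  tibble::tibble(
    patient_id = sprintf("P%02d", 1:n),
    age_at_mri = rnorm(n, 60, 10),
    sex = factor(sample(c("M", "F"), n, replace = TRUE), c("F", "M")),
    onset_site = factor(sample(c("bulbar", "spinal"), n, replace = TRUE),
                        c("spinal", "bulbar")),
    t_mri_months = runif(n, 5, 40),
    d50 = rlnorm(n, log(30), 0.5),
    phase = factor(rep(c("I", "II"), c(n_g1, n_g2)), c("I", "II", "III_IV"))
  ) |>
    dplyr::mutate(rd50_at_mri = rd50_at(d50, t_mri_months),
                  aggressiveness = classify_aggressiveness(d50))
}

rand_maps <- function(n, shape, seed = 30) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    masked_volume(array(rnorm(prod(shape)), shape))
  })
}

test_that("design matrices carry the stated covariate structure", {
  rec <- make_records(5, 5)
  d <- build_design(rec, "phase_contrast")
  expect_identical(c(d$n, d$p), c(10L, 6L))
  expect_identical(colnames(d$X),
                   c("g1", "g2", "sex", "age", "onset", "congruent"))
  expect_equal(d$contrast, c(1, -1, 0, 0, 0, 0))
  expect_equal(unname(colMeans(d$X[, c("age", "congruent")])), c(0, 0))
  # HC comparisons use exactly age and sex as nuisance
  hc <- tibble::tibble(age_at_mri = rnorm(8, 55, 10),
                       sex = factor(rep(c("M", "F"), 4)))
  dh <- build_design(rec, "vs_hc_contrast", controls = hc)
  expect_identical(colnames(dh$X), c("patients", "hc", "sex", "age"))
  expect_identical(dh$p, 4L)
  # congruent-parameter rule: rD50 regression carries a D50 nuisance column
  dr <- build_design(rec, "regress_rd50")
  expect_identical(dr$p, 6L)
  expect_true("congruent" %in% colnames(dr$X))
})

test_that("degenerate designs are rejected with informative errors", {
  rec <- make_records(5, 5)
  expect_error(build_design(dplyr::select(rec, -d50), "phase_contrast"),
               "missing covariate")
  rec_one <- make_records(10, 0)
  rec_one$phase <- factor("I", levels = c("I", "II", "III_IV"))
  expect_error(build_design(rec_one, "phase_contrast"), "empty")
  rec_const <- make_records(5, 5)
  rec_const$sex <- factor("M", levels = c("F", "M"))
  expect_error(build_design(rec_const, "phase_contrast"), "constant")
  expect_error(build_design(rec, "vs_hc_contrast"), "controls")
})

test_that("patients beyond Phase II are dropped from the phase contrast", {
  rec <- make_records(5, 5)
  rec$phase[1] <- "III_IV"
  expect_warning(d <- build_design(rec, "phase_contrast"), "beyond Phase II")
  expect_identical(d$n, 9L)
})

test_that("voxel-wise t equals the per-voxel lm oracle", {
  rec <- make_records(10, 10, seed = 21)
  d <- build_design(rec, "phase_contrast")
  maps <- rand_maps(20, c(5, 5, 5), seed = 31)
  tm <- fit_voxelwise_glm(maps, d)
  expect_identical(tm$df, 20L - 6L)
  Y <- sapply(maps, function(m) m$data[tm$mask])
  for (v in sample(nrow(Y), 20)) {
    expect_equal(tm$t[tm$mask][v], oracle_voxel_t(d$X, Y[v, ], d$contrast),
                 tolerance = 1e-8)
  }
})

test_that("zero residual variance yields the infinity marker", {
  shape <- c(2, 2, 2)
  maps <- lapply(rep(c(5, 3), each = 10), function(val) {
    masked_volume(array(val, shape))
  })
  subj <- tibble::tibble(subject_id = 1:20, group = rep(c("A", "B"), each = 10))
  d <- build_design(subj, "group_contrast")
  tm <- fit_voxelwise_glm(maps, d)
  expect_true(all(tm$t[tm$mask] == Inf))
  tm_neg <- fit_voxelwise_glm(maps, d, contrast = -d$contrast)
  expect_true(all(tm_neg$t[tm_neg$mask] == -Inf))
})

test_that("contrasts behave linearly and designs are permutation-consistent", {
  rec <- make_records(8, 8, seed = 22)
  d <- build_design(rec, "regress_rd50")
  maps <- rand_maps(16, c(4, 4, 4), seed = 32)
  tm <- fit_voxelwise_glm(maps, d)
  # negating the contrast negates the map exactly
  tm_neg <- fit_voxelwise_glm(maps, d, contrast = -d$contrast)
  expect_equal(tm_neg$t, -tm$t)
  # contrast orthogonal to every varying regressor gives t = 0... use a
  # contrast on a column whose coefficient is unpenalised: zero contrast
  tm0 <- fit_voxelwise_glm(maps, d, contrast = rep(0, d$p))
  expect_true(all(tm0$t[tm0$mask] == 0))
  # permuting subjects jointly in maps and design rows leaves t unchanged
  set.seed(5)
  perm <- sample(16)
  rec_p <- rec[perm, ]
  d_p <- build_design(rec_p, "regress_rd50")
  tm_p <- fit_voxelwise_glm(maps[perm], d_p)
  expect_equal(tm_p$t, tm$t, tolerance = 1e-10)
})

test_that("an orthogonal nuisance column only rescales t via the df change", {
  set.seed(33)
  n <- 16
  X <- cbind(g1 = rep(c(1, 0), each = n / 2), g2 = rep(c(0, 1), each = n / 2))
  y <- rnorm(n)
  # build a column orthogonal to the design AND the data
  z <- rnorm(n)
  z <- resid(lm(z ~ X + y - 1))
  d1 <- structure(list(X = X, contrast = c(1, -1), labels = c("a", "b"),
                       effect = "group_contrast", n = n, p = 2L, ids = 1:n),
                  class = "vx_design")
  X2 <- cbind(X, z = z)
  d2 <- structure(list(X = X2, contrast = c(1, -1, 0), labels = c("a", "b"),
                       effect = "group_contrast", n = n, p = 3L, ids = 1:n),
                  class = "vx_design")
  maps <- lapply(y, function(val) masked_volume(array(val, c(1, 1, 1))))
  t1 <- fit_voxelwise_glm(maps, d1)$t[1, 1, 1]
  t2 <- fit_voxelwise_glm(maps, d2)$t[1, 1, 1]
  expect_equal(t2, t1 * sqrt((n - 3) / (n - 2)), tolerance = 1e-10)
})

test_that("null Gaussian maps give a calibrated supra-threshold rate", {
  # ~2.1e6 voxel-tests pooled over both one-sided directions
  set.seed(77)
  shape <- c(33, 33, 33)
  subj <- tibble::tibble(subject_id = 1:20, group = rep(c("A", "B"), each = 10))
  d <- build_design(subj, "group_contrast")
  hits <- 0
  total <- 0
  for (rep in 1:30) {
    maps <- lapply(1:20, function(i) {
      masked_volume(array(rnorm(prod(shape)), shape))
    })
    tm <- fit_voxelwise_glm(maps, d)
    co <- qt(1 - 5e-4, tm$df)
    tv <- tm$t[tm$mask]
    hits <- hits + sum(tv > co) + sum(-tv > co)
    total <- total + 2 * length(tv)
  }
  expect_gte(total, 2e6)
  p0 <- 5e-4
  expect_lt(abs(hits / total - p0), 3 * sqrt(p0 * (1 - p0) / total))
})

test_that("maps undefined in one subject are excluded from the common mask", {
  maps <- rand_maps(12, c(3, 3, 3), seed = 34)
  maps[[4]]$data[2, 2, 2] <- NA
  maps[[4]]$mask[1, 1, 1] <- FALSE
  subj <- tibble::tibble(subject_id = 1:12, group = rep(c("A", "B"), each = 6))
  tm <- fit_voxelwise_glm(maps, build_design(subj, "group_contrast"))
  expect_false(tm$mask[2, 2, 2])
  expect_false(tm$mask[1, 1, 1])
  expect_identical(sum(tm$mask), 25L)
})
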