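#' Simulate an ALS cohort with D50-model structure
#'
#' Draws per-patient true sigmoid parameters, an MRI scan time, covariates
#' and a noisy ALSFRS-R visit series, emulating the marginal structure of a
#' representative clinic cohort: a right-skewed D50 (log-normal,
#' parameterised by its median with the spread matched numerically to a
#' target inter-quartile range), a Beta-distributed disease accumulation at
#' scan (mean 0.28, sd 0.13, truncated to the observed 0.05-0.70 range, so
#' roughly 42%/55% of patients fall in Phases I/II), and sex/onset/age
#' marginals matching the cohort frequencies. Visit scores are
#' `round(clip(F(t) + noise, 0, 48))`.
#'
#' @param n number of patients (default 116).
#' @param d50_median,d50_iqr target median and IQR of true D50 in months.
#' @param dx_median,dx_sdlog log-normal parameters of the sigmoid time
#'   constant (median 6 months — a typical decline spanning roughly two
#'   years around D50).
#' @param rd50_mean,rd50_sd,rd50_range Beta-distribution moments and
#'   truncation range of disease accumulation at the scan.
#' @param n_visits,visit_interval,visit_jitter visit schedule: `n_visits`
#'   visits starting near the scan, nominally `visit_interval` months apart
#'   with uniform jitter of +/- `visit_jitter` months.
#' @param score_sd additive observation noise (ALSFRS-R points) before
#'   rounding/clipping.
#' @param p_male,p_bulbar sex and onset-site marginals.
#' @param age_mean,age_sd,age_range truncated-normal age-at-MRI parameters.
#' @param seed integer seed; identical seeds give identical cohorts.
#' @return a list of class `als_cohort` with tibbles `patients`
#'   (`patient_id`, `age_at_mri`, `sex`, `onset_site`, `t_mri_months`, plus
#'   the generating truth `d50_true`, `dx_true`, `rd50_true`) and `scores`
#'   (`patient_id`, `t_months`, `alsfrs_r`).
#' @examples
#' coh <- simulate_cohort(n = 20, seed = 1)
#' head(coh$scores)
#' @export
simulate_cohort <- function(n = 116,
                            d50_median = 30.23, d50_iqr = 22.53,
                            dx_median = 6, dx_sdlog = 0.4,
                            rd50_mean = 0.28, rd50_sd = 0.13,
                            rd50_range = c(0.05, 0.70),
                            n_visits = 5, visit_interval = 3,
                            visit_jitter = 0.5, score_sd = 2,
                            p_male = 69 / 116, p_bulbar = 34 / 116,
                            age_mean = 63.08, age_sd = 15.36,
                            age_range = c(27.25, 82.91),
                            seed = NULL) {
  stop_if(n < 1, "`n` must be >= 1")
  stop_if(d50_median <= 0 || d50_iqr <= 0 || dx_median <= 0,
          "scale parameters must be positive")
  stop_if(p_male < 0 || p_male > 1 || p_bulbar < 0 || p_bulbar > 1,
          "probabilities must lie in [0, 1]")
  stop_if(visit_jitter >= visit_interval / 2,
          "`visit_jitter` must be < visit_interval / 2 to keep times increasing")
  if (!is.null(seed)) set.seed(seed)

  # log-normal sigma solved so that the IQR matches the target
  z75 <- stats::qnorm(0.75)
  sdlog <- uniroot(
    function(s) d50_median * (exp(z75 * s) - exp(-z75 * s)) - d50_iqr,
    c(1e-4, 5)
  )$root
  d50_true <- rlnorm(n, log(d50_median), sdlog)
  dx_true <- rlnorm(n, log(dx_median), dx_sdlog)

  # Beta moments -> shape parameters; truncated by rejection
  k <- rd50_mean * (1 - rd50_mean) / rd50_sd^2 - 1
  stop_if(k <= 0, "rd50 moments imply a non-positive Beta concentration")
  a <- rd50_mean * k
  b <- (1 - rd50_mean) * k
  rd50_true <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    draw <- rbeta(length(todo), a, b)
    ok <- draw >= rd50_range[1] & draw <= rd50_range[2]
    rd50_true[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }
  t_mri <- 2 * d50_true * rd50_true

  age <- numeric(n)
  todo <- seq_len(n)
  while (length(todo) > 0) {
    draw <- rnorm(length(todo), age_mean, age_sd)
    ok <- draw >= age_range[1] & draw <= age_range[2]
    age[todo[ok]] <- draw[ok]
    todo <- todo[!ok]
  }

  ids <- sprintf("P%03d", seq_len(n))
  patients <- tibble(
    patient_id = ids,
    age_at_mri = age,
    sex = factor(ifelse(runif(n) < p_male, "M", "F"), levels = c("F", "M")),
    onset_site = factor(ifelse(runif(n) < p_bulbar, "bulbar", "spinal"),
                        levels = c("spinal", "bulbar")),
    t_mri_months = t_mri,
    d50_true = d50_true,
    dx_true = dx_true,
    rd50_true = rd50_true
  )

  scores <- purrr::map_dfr(seq_len(n), function(i) {
    gaps <- visit_interval + runif(n_visits - 1, -visit_jitter, visit_jitter)
    t0 <- max(1, t_mri[i] - visit_interval)
    tv <- t0 + c(0, cumsum(gaps))
    s <- alsfrs_sigmoid(tv, d50_true[i], dx_true[i]) +
      rnorm(n_visits, 0, score_sd)
    tibble(patient_id = ids[i], t_months = tv,
           alsfrs_r = as.integer(round(pmin(pmax(s, 0), 48))))
  })

  structure(list(patients = patients, scores = scores), class = "als_cohort")
}

#' @export
print.als_cohort <- function(x, ...) {
  cat(sprintf("<als_cohort> %d patients, %d visits\n",
              nrow(x$patients), nrow(x$scores)))
  invisible(x)
}

# n voxels nearest `center` (in voxel units) -> logical ROI array
roi_sphere <- function(shape, center, n_voxels) {
  g <- expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                   k = seq_len(shape[3]))
  d2 <- (g$i - center[1])^2 + (g$j - center[2])^2 + (g$k - center[3])^2
  roi <- array(FALSE, shape)
  roi[order(d2)[seq_len(n_voxels)]] <- TRUE
  roi
}

ellipsoid_mask <- function(shape, semi_axes = (shape - 2) / 2) {
  ctr <- (shape + 1) / 2
  g <- expand.grid(i = seq_len(shape[1]), j = seq_len(shape[2]),
                   k = seq_len(shape[3]))
  inside <- ((g$i - ctr[1]) / semi_axes[1])^2 +
    ((g$j - ctr[2]) / semi_axes[2])^2 +
    ((g$k - ctr[3]) / semi_axes[3])^2 <= 1
  array(inside, shape)
}

#' Simulate 3D texture phantoms with a group-dependent ROI effect
#'
#' Each subject's volume is spatially smoothed Gaussian noise inside an
#' ellipsoidal analysis mask. Inside a spherical region of interest the
#' noise is smoothed at the subject's group-specific strength instead, so
#' groups differ in local spatial autocorrelation — the image property the
#' GLCM autocorrelation feature responds to — rather than in mean intensity,
#' which global min-max quantization would largely absorb. Every smoothed
#' field is rank-standardised to uniform marginals on (0, 1) (a probability
#' integral transform) before composition. This emulates the global
#' intensity standardisation applied upstream of texture analysis in real
#' T1 pipelines and pins the per-subject min-max quantization range: without
#' it the sample extremes — and hence the level-bin edges — jitter between
#' subjects, injecting a common intensity-scale noise component into every
#' voxel of the texture map. Equal group smoothing strengths (`fwhm_roi`
#' all equal to `fwhm_background`) give an exchangeable null.
#'
#' @param groups character or factor of group labels, one per subject (e.g.
#'   `rep(c("A", "B"), each = 20)`).
#' @param shape grid dimensions (default `c(32, 32, 32)`).
#' @param roi_n_voxels ROI size in voxels (default 500).
#' @param roi_center ROI centre in voxel coordinates; defaults to the grid
#'   centre.
#' @param fwhm_background Gaussian smoothing FWHM (voxels) outside the ROI,
#'   all groups (default 0.5).
#' @param fwhm_roi named numeric of per-group ROI smoothing FWHM (voxels);
#'   default gives the first group 2.0 and all others 0.5.
#' @param intensity_offset constant added to every volume.
#' @param voxel_size mm per axis for the generated volumes.
#' @param seed integer seed; per-subject sub-seeds are split from it.
#' @return a list of class `phantom_set`: `volumes` (list of
#'   [masked_volume()]), `subjects` (tibble `subject_id`, `group`), `roi`
#'   and `mask` (logical arrays), and the config.
#' @examples
#' ph <- simulate_phantoms(rep(c("A", "B"), each = 2), shape = c(16, 16, 16),
#'                         roi_n_voxels = 50, seed = 1)
#' length(ph$volumes)
#' @export
simulate_phantoms <- function(groups, shape = c(32, 32, 32),
                              roi_n_voxels = 500, roi_center = NULL,
                              fwhm_background = 0.5, fwhm_roi = NULL,
                              intensity_offset = 0, voxel_size = c(1, 1, 1),
                              seed = NULL) {
  groups <- as.factor(groups)
  n <- length(groups)
  stop_if(n < 2, "need at least 2 subjects")
  stop_if(fwhm_background < 0, "smoothing strengths must be >= 0")
  lev <- levels(groups)
  if (is.null(fwhm_roi)) {
    fwhm_roi <- setNames(c(2.0, rep(0.5, length(lev) - 1)), lev)
  }
  stop_if(!all(lev %in% names(fwhm_roi)),
          "`fwhm_roi` must name every group")
  stop_if(any(fwhm_roi < 0), "smoothing strengths must be >= 0")
  if (!is.null(seed)) set.seed(seed)

  mask <- ellipsoid_mask(shape)
  if (is.null(roi_center)) roi_center <- (shape + 1) / 2
  roi <- roi_sphere(shape, roi_center, roi_n_voxels)
  stop_if(any(roi & !mask), "ROI extends outside the analysis mask")

  fwhm2sigma <- 1 / (2 * sqrt(2 * log(2)))
  # probability integral transform: uniform marginals, fixed global range
  standardise <- function(x) stats::pnorm((x - mean(x)) / sd(x))
  sub_seeds <- split_seeds(n)

  volumes <- purrr::map(seq_len(n), function(i) {
    set.seed(sub_seeds[i])
    nvox <- prod(shape)
    bg <- smooth3d_cpp(rnorm(nvox), as.integer(shape),
                       fwhm_background * fwhm2sigma)
    bg <- standardise(bg)
    fr <- fwhm_roi[[as.character(groups[i])]]
    rf <- smooth3d_cpp(rnorm(nvox), as.integer(shape), fr * fwhm2sigma)
    rf <- standardise(rf)
    dat <- array(bg, shape)
    dat[roi] <- rf[roi]
    dat <- dat + intensity_offset
    dat[!mask] <- 0
    masked_volume(dat, mask, voxel_size = voxel_size)
  })

  structure(
    list(volumes = volumes,
         subjects = tibble(subject_id = sprintf("S%03d", seq_len(n)),
                           group = groups),
         roi = roi, mask = mask,
         config = list(shape = shape, roi_n_voxels = roi_n_voxels,
                       roi_center = roi_center,
                       fwhm_background = fwhm_background,
                       fwhm_roi = fwhm_roi,
                       intensity_offset = intensity_offset, seed = seed)),
    class = "phantom_set"
  )
}

#' @export
print.phantom_set <- function(x, ...) {
  cat(sprintf("<phantom_set> %d subjects (%s), grid %s, ROI %d voxels\n",
              nrow(x$subjects),
              paste(levels(x$subjects$group), collapse = "/"),
              paste(x$config$shape, collapse = "x"),
              sum(x$roi)))
  invisible(x)
}
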