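#' Sigmoidal ALSFRS-R decline curve
#'
#' The D50 model describes functional decline as a sigmoid from full health
#' (score 48) to complete functional loss:
#' `F(t) = 48 / (1 + exp((t - D50) / dx))`, where `D50` is the time in
#' months from symptom onset at which half of motor function (score 24) is
#' lost, and `dx` is the time constant of the decline around `D50`.
#'
#' @param t months since symptom onset.
#' @param d50 months until half of function is lost (> 0).
#' @param dx sigmoid time constant in months (> 0).
#' @return predicted ALSFRS-R score(s).
#' @examples
#' alsfrs_sigmoid(30, d50 = 30, dx = 6) # 24 by definition
#' @export
alsfrs_sigmoid <- function(t, d50, dx) {
  48 / (1 + exp((t - d50) / dx))
}

#' Fit the D50 progression model to one ALSFRS-R series
#'
#' Bounded nonlinear least squares on `F(t) = 48 / (1 + exp((t - D50)/dx))`,
#' multi-started from three D50 initialisations (the last observed time,
#' twice the last observed time, and the time the score crosses 24 by linear
#' interpolation) to avoid local minima in flat-tail series. By default a
#' virtual full-health anchor observation (t = 0, score = 48) is prepended,
#' reflecting the model's premise that decline starts from full health; it
#' stabilises fits of short series and can be disabled.
#'
#' @param t months since symptom onset; non-negative, strictly increasing.
#' @param score ALSFRS-R scores in `[0, 48]`, same length as `t`.
#' @param anchor prepend the (0, 48) full-health anchor (skipped when an
#'   observation at t = 0 already exists). Default `TRUE`.
#' @param min_obs minimum number of real observations required (default 2;
#'   two points plus the anchor identify the two parameters).
#' @param d50_bounds,dx_bounds solver box constraints in months.
#' @return an object of class `d50_fit` with elements `d50`, `dx`, `rss`,
#'   `n_obs` (real observations used), `converged`, and the fitted data.
#' @examples
#' t <- seq(0, 48, by = 6)
#' fit <- fit_d50(t, alsfrs_sigmoid(t, 30, 6))
#' fit$d50
#' @export
fit_d50 <- function(t, score, anchor = TRUE, min_obs = 2,
                    d50_bounds = c(0.5, 500), dx_bounds = c(0.1, 100)) {
  stop_if(length(t) != length(score), "`t` and `score` lengths differ")
  stop_if(length(t) < min_obs,
          sprintf("need at least %d observations, got %d", min_obs,
                  length(t)))
  stop_if(any(t < 0), "observation times must be >= 0")
  stop_if(any(diff(t) <= 0), "observation times must be strictly increasing")
  stop_if(any(score < 0 | score > 48), "scores must lie in [0, 48]")
  n_obs <- length(t)

  tf <- t
  sf <- score
  if (isTRUE(anchor) && tf[1] > 0) {
    tf <- c(0, tf)
    sf <- c(48, sf)
  }

  # multi-start D50 initialisations
  t_last <- max(t)
  cross24 <- tryCatch(
    approx(x = sf, y = tf, xout = 24, ties = mean, rule = 2)$y,
    error = function(e) t_last
  )
  starts <- unique(pmin(pmax(c(t_last, 2 * t_last, cross24), d50_bounds[1]),
                        d50_bounds[2]))
  dx0 <- min(max((max(tf) - min(tf)) / 4, dx_bounds[1]), dx_bounds[2])

  dat <- data.frame(t = tf, score = sf)
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        score ~ 48 / (1 + exp((t - d50) / dx)),
        data = dat, start = list(d50 = s, dx = dx0),
        lower = c(d50_bounds[1], dx_bounds[1]),
        upper = c(d50_bounds[2], dx_bounds[2]),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(fit)) next
    rss <- sum(resid(fit)^2)
    if (is.null(best) || rss < best$rss) {
      cf <- coef(fit)
      best <- list(d50 = unname(cf["d50"]), dx = unname(cf["dx"]), rss = rss,
                   converged = isTRUE(fit$convInfo$isConv))
    }
  }

  if (is.null(best)) {
    # all solver starts failed: fall back to a coarse profile search so the
    # best-found parameters are still reported (flagged non-converged)
    g <- expand.grid(
      d50 = exp(seq(log(d50_bounds[1]), log(d50_bounds[2]), length.out = 120)),
      dx = exp(seq(log(dx_bounds[1]), log(dx_bounds[2]), length.out = 60))
    )
    rss <- vapply(seq_len(nrow(g)), function(i) {
      sum((sf - alsfrs_sigmoid(tf, g$d50[i], g$dx[i]))^2)
    }, numeric(1))
    i <- which.min(rss)
    best <- list(d50 = g$d50[i], dx = g$dx[i], rss = rss[i], converged = FALSE)
  }

  structure(
    list(d50 = best$d50, dx = best$dx, rss = best$rss, n_obs = n_obs,
         converged = best$converged, anchored = isTRUE(anchor) && t[1] > 0,
         data = tibble(t = t, score = score)),
    class = "d50_fit"
  )
}

#' @export
print.d50_fit <- function(x, ...) {
  cat(sprintf(
    "<d50_fit> D50 = %.2f months, dx = %.2f, RSS = %.3f, n = %d%s\n",
    x$d50, x$dx, x$rss, x$n_obs,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Relative D50 (disease accumulation) at a time point
#'
#' Normalises time since onset so that the value is 0.5 at `t = D50`:
#' `rD50 = t / (2 * D50)`. rD50 measures how much of the individual disease
#' course has accumulated, independently of how aggressive the course is.
#'
#' @param fit a [fit_d50()] result, or a numeric D50 value (months, > 0).
#' @param t months since onset (>= 0); vectorised.
#' @return rD50 value(s) in `[0, Inf)`.
#' @examples
#' rd50_at(30, c(0, 15, 30)) # 0, 0.25, 0.5
#' @export
rd50_at <- function(fit, t) {
  d50 <- if (inherits(fit, "d50_fit")) fit$d50 else fit
  stop_if(any(d50 <= 0), "D50 must be positive")
  stop_if(any(t < 0), "`t` must be >= 0")
  t / (2 * d50)
}

#' Classify disease phase from rD50
#'
#' Phase I (early semi-stable) for rD50 < 0.25, Phase II (early progressive)
#' for 0.25 <= rD50 < 0.50, Phases III/IV (late progressive or stable) for
#' rD50 >= 0.50. Half-open intervals: the boundaries 0.25 and 0.50 belong to
#' the upper phase.
#'
#' @param rd50 rD50 value(s), >= 0.
#' @return factor with levels `I`, `II`, `III_IV`.
#' @examples
#' classify_phase(c(0.2, 0.25, 0.55))
#' @export
classify_phase <- function(rd50) {
  stop_if(any(rd50 < 0), "rD50 must be >= 0")
  cut(rd50, breaks = c(-Inf, 0.25, 0.50, Inf), right = FALSE,
      labels = c("I", "II", "III_IV"))
}

#' Classify disease aggressiveness from D50
#'
#' Low aggressiveness (LA) for D50 > 30 months, high aggressiveness (HA) for
#' D50 <= 30 months. The boundary value 30 is HA by default; published
#' renderings of the split differ on boundary membership, so it is
#' configurable.
#'
#' @param d50 D50 value(s) in months, > 0.
#' @param boundary class assigned at exactly D50 = 30 (`"HA"` default).
#' @return factor with levels `LA`, `HA`.
#' @examples
#' classify_aggressiveness(c(20, 30, 31))
#' @export
classify_aggressiveness <- function(d50, boundary = c("HA", "LA")) {
  boundary <- match.arg(boundary)
  stop_if(any(d50 <= 0), "D50 must be positive")
  la <- if (boundary == "HA") d50 > 30 else d50 >= 30
  factor(ifelse(la, "LA", "HA"), levels = c("LA", "HA"))
}

#' Fit the D50 model across a cohort
#'
#' Fits [fit_d50()] per patient from a long table of ALSFRS-R visits and, if
#' a patient table is supplied, derives rD50 at the MRI time point, the
#' disease phase and the aggressiveness class.
#'
#' @param scores data frame with columns `patient_id`, `t_months`,
#'   `alsfrs_r` (one row per visit).
#' @param patients optional data frame with columns `patient_id`,
#'   `age_at_mri`, `sex`, `onset_site`, `t_mri_months`.
#' @param ... passed to [fit_d50()].
#' @return a tibble with one row per patient: `patient_id`, `d50`, `dx`,
#'   `rss`, `n_obs`, `converged`, and (with `patients`) the covariates plus
#'   `rd50_at_mri`, `phase`, `aggressiveness`.
#' @export
fit_d50_cohort <- function(scores, patients = NULL, ...) {
  stop_if(!all(c("patient_id", "t_months", "alsfrs_r") %in% names(scores)),
          "`scores` needs columns patient_id, t_months, alsfrs_r")
  fits <- scores |>
    dplyr::arrange(.data$patient_id, .data$t_months) |>
    dplyr::group_by(.data$patient_id) |>
    dplyr::group_modify(function(d, key) {
      f <- fit_d50(d$t_months, d$alsfrs_r, ...)
      tibble(d50 = f$d50, dx = f$dx, rss = f$rss, n_obs = f$n_obs,
             converged = f$converged)
    }) |>
    dplyr::ungroup()
  if (is.null(patients)) {
    return(fits)
  }
  stop_if(!all(c("patient_id", "t_mri_months") %in% names(patients)),
          "`patients` needs columns patient_id, t_mri_months")
  fits |>
    dplyr::inner_join(patients, by = "patient_id") |>
    dplyr::mutate(
      rd50_at_mri = rd50_at(.data$d50, .data$t_mri_months),
      phase = classify_phase(.data$rd50_at_mri),
      aggressiveness = classify_aggressiveness(.data$d50)
    )
}
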