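#' Build a voxel-wise GLM design from patient records
#'
#' Encodes the requested effect of interest plus the nuisance covariates
#' used throughout the analysis: sex and onset site as 0/1 indicators, age
#' mean-centred, and the congruent progression parameter mean-centred (D50
#' when the effect under analysis derives from rD50, and vice versa). Group
#' contrasts are encoded as two group-indicator columns (no intercept) with
#' contrast vector `(1, -1, 0, ...)`; regressions carry an intercept and a
#' mean-centred effect column with contrast `(0, 1, 0, ...)`. Comparisons
#' against healthy controls use age and sex as the only nuisance covariates.
#'
#' @param patients tibble of patient records (the [fit_d50_cohort()]
#'   schema: `sex`, `age_at_mri`, `onset_site`, `d50`, `rd50_at_mri`,
#'   `phase`, `aggressiveness` as required by the effect). For
#'   `phase_contrast` only Phase I and II patients enter; later-phase
#'   patients are dropped with a warning.
#' @param effect one of `phase_contrast` (I vs II), `aggressiveness_contrast`
#'   (HA vs LA), `onset_contrast` (bulbar vs spinal; sex and age nuisance),
#'   `vs_hc_contrast` (patients vs `controls`; age and sex nuisance),
#'   `regress_d50`, `regress_rd50`, or `group_contrast` (generic two-group
#'   via a `group` column, no covariates — used for phantom studies).
#' @param controls tibble of healthy controls (`age_at_mri`, `sex`);
#'   required for `vs_hc_contrast`.
#' @return an object of class `vx_design`: design matrix `X` (n x p),
#'   `contrast` (the positive-direction contrast vector), `labels` of the
#'   contrast directions, `effect`, `n`, `p`, and the subject order.
#' @export
build_design <- function(patients,
                         effect = c("phase_contrast",
                                    "aggressiveness_contrast",
                                    "onset_contrast", "vs_hc_contrast",
                                    "regress_d50", "regress_rd50",
                                    "group_contrast"),
                         controls = NULL) {
  effect <- match.arg(effect)
  need <- function(cols, where = patients) {
    miss <- setdiff(cols, names(where))
    stop_if(length(miss) > 0,
            paste0("missing covariate column(s): ",
                   paste(miss, collapse = ", ")))
    stop_if(anyNA(where[cols]), "covariates contain missing values")
  }
  sex01 <- function(x) as.numeric(x == "M")
  onset01 <- function(x) as.numeric(x == "bulbar")
  ctr <- function(x) x - mean(x)

  if (effect == "group_contrast") {
    need("group")
    g <- droplevels(as.factor(patients$group))
    stop_if(nlevels(g) != 2, "`group` must have exactly 2 levels")
    X <- cbind(g1 = as.numeric(g == levels(g)[1]),
               g2 = as.numeric(g == levels(g)[2]))
    contrast <- c(1, -1)
    labels <- c(paste0(levels(g)[1], " > ", levels(g)[2]),
                paste0(levels(g)[2], " > ", levels(g)[1]))
    ids <- if ("subject_id" %in% names(patients)) patients$subject_id
           else seq_len(nrow(patients))
  } else if (effect == "vs_hc_contrast") {
    stop_if(is.null(controls), "`controls` required for vs_hc_contrast")
    need(c("age_at_mri", "sex"))
    need(c("age_at_mri", "sex"), controls)
    age <- c(patients$age_at_mri, controls$age_at_mri)
    sex <- c(sex01(patients$sex), sex01(controls$sex))
    np <- nrow(patients)
    nh <- nrow(controls)
    X <- cbind(patients = rep(c(1, 0), c(np, nh)),
               hc = rep(c(0, 1), c(np, nh)),
               sex = sex, age = ctr(age))
    contrast <- c(1, -1, 0, 0)
    labels <- c("patients > HC", "HC > patients")
    ids <- c(as.character(patients$patient_id), paste0("HC", seq_len(nh)))
  } else if (effect %in% c("phase_contrast", "aggressiveness_contrast",
                           "onset_contrast")) {
    base_cols <- c("sex", "age_at_mri")
    grp <- switch(effect,
      phase_contrast = {
        need(c(base_cols, "onset_site", "phase", "d50"))
        keep <- patients$phase %in% c("I", "II")
        if (!all(keep)) {
          warn(sprintf("dropping %d patient(s) beyond Phase II", sum(!keep)))
          patients <- patients[keep, , drop = FALSE]
        }
        list(g = factor(patients$phase, levels = c("I", "II")),
             congruent = patients$d50)
      },
      aggressiveness_contrast = {
        need(c(base_cols, "onset_site", "aggressiveness", "rd50_at_mri"))
        list(g = factor(patients$aggressiveness, levels = c("HA", "LA")),
             congruent = patients$rd50_at_mri)
      },
      onset_contrast = {
        need(c(base_cols, "onset_site"))
        list(g = factor(patients$onset_site, levels = c("bulbar", "spinal")),
             congruent = NULL)
      })
    g <- grp$g
    stop_if(any(table(g) == 0), "a contrast group is empty")
    X <- cbind(g1 = as.numeric(g == levels(g)[1]),
               g2 = as.numeric(g == levels(g)[2]),
               sex = sex01(patients$sex),
               age = ctr(patients$age_at_mri))
    if (effect != "onset_contrast") {
      X <- cbind(X, onset = onset01(patients$onset_site),
                 congruent = ctr(grp$congruent))
    }
    contrast <- c(1, -1, rep(0, ncol(X) - 2))
    labels <- c(paste0(levels(g)[1], " > ", levels(g)[2]),
                paste0(levels(g)[2], " > ", levels(g)[1]))
    ids <- as.character(patients$patient_id)
  } else { # regressions
    eff_col <- if (effect == "regress_d50") "d50" else "rd50_at_mri"
    cong_col <- if (effect == "regress_d50") "rd50_at_mri" else "d50"
    need(c("sex", "age_at_mri", "onset_site", eff_col, cong_col))
    X <- cbind(intercept = 1,
               effect = ctr(patients[[eff_col]]),
               sex = sex01(patients$sex),
               age = ctr(patients$age_at_mri),
               onset = onset01(patients$onset_site),
               congruent = ctr(patients[[cong_col]]))
    contrast <- c(0, 1, rep(0, ncol(X) - 2))
    lab <- if (effect == "regress_d50") "D50" else "rD50"
    labels <- c(paste0("positive ", lab, " association"),
                paste0("negative ", lab, " association"))
    ids <- as.character(patients$patient_id)
  }

  n <- nrow(X)
  p <- ncol(X)
  stop_if(n <= p, "design needs more subjects than regressors")
  const <- apply(X, 2, function(col) stats::var(col) == 0)
  stop_if(any(const & colnames(X) %in% c("sex", "age", "onset", "congruent",
                                          "effect")),
          "a non-intercept design column is constant")
  stop_if(qr(X)$rank < p, "design matrix is rank deficient")

  structure(
    list(X = X, contrast = contrast, labels = labels, effect = effect,
         n = n, p = p, ids = ids),
    class = "vx_design"
  )
}

#' @export
print.vx_design <- function(x, ...) {
  cat(sprintf("<vx_design> %s: n = %d, p = %d [%s]\n", x$effect, x$n, x$p,
              paste(colnames(x$X), collapse = ", ")))
  invisible(x)
}

#' Mass-univariate GLM over texture maps
#'
#' Per-voxel ordinary least squares of the subject maps on the design, with
#' `t = c'b / sqrt(s2 * c'(X'X)^-1 c)` and `df = n - p`. The common analysis
#' mask is the intersection of every map's defined voxels: a voxel undefined
#' in any subject is excluded. Voxels with zero residual variance get
#' `t = +/- Inf` (sign of the estimated effect; 0 when the effect is also
#' zero) — an explicit marker rather than a silent drop.
#'
#' @param maps list of `texture_map` (or `masked_volume`) objects, one per
#'   design row, on a common grid.
#' @param design a [build_design()] result.
#' @param contrast contrast vector of length p; defaults to the design's
#'   positive-direction contrast. Negate it for the opposite direction.
#' @param label optional contrast label for reporting.
#' @return an object of class `t_map`: `t` (3D array, `NA` outside the
#'   common mask), `df`, `mask`, `contrast`, `label`, `voxel_size`,
#'   `affine`.
#' @export
fit_voxelwise_glm <- function(maps, design, contrast = NULL, label = NULL) {
  stop_if(!inherits(design, "vx_design"), "`design` must be a vx_design")
  stop_if(length(maps) != design$n,
          sprintf("got %d maps for %d design rows", length(maps), design$n))
  if (is.null(contrast)) contrast <- design$contrast
  stop_if(length(contrast) != design$p, "contrast length must equal p")
  if (is.null(label)) {
    label <- if (identical(as.numeric(contrast), as.numeric(design$contrast)))
      design$labels[1]
    else if (identical(as.numeric(contrast), -as.numeric(design$contrast)))
      design$labels[2]
    else "custom contrast"
  }

  dims <- dim(maps[[1]]$data)
  for (m in maps) {
    stop_if(!identical(dim(m$data), dims), "maps are not on a common grid")
  }
  mask <- Reduce(`&`, lapply(maps, function(m) m$mask & !is.na(m$data)))
  stop_if(!any(mask), "no voxel is defined in every subject")

  Y <- vapply(maps, function(m) m$data[mask], numeric(sum(mask)))
  Y <- t(matrix(Y, nrow = sum(mask))) # n x V (robust to single-voxel masks)
  X <- design$X
  n <- design$n
  p <- design$p
  df <- n - p
  XtXinv <- chol2inv(chol(crossprod(X)))
  B <- XtXinv %*% crossprod(X, Y)          # p x V
  res <- Y - X %*% B
  sigma2 <- colSums(res^2) / df
  num <- drop(crossprod(contrast, B))      # c'b per voxel
  se <- sqrt(sigma2 * drop(t(contrast) %*% XtXinv %*% contrast))
  tval <- ifelse(se > 0, num / se, sign(num) * Inf)
  tval[se == 0 & num == 0] <- 0

  tarr <- array(NA_real_, dims)
  tarr[mask] <- tval
  structure(
    list(t = tarr, df = df, mask = mask, contrast = contrast, label = label,
         effect = design$effect,
         voxel_size = maps[[1]]$voxel_size, affine = maps[[1]]$affine),
    class = "t_map"
  )
}

#' @export
print.t_map <- function(x, ...) {
  cat(sprintf("<t_map> %s (%s), df = %d, %d voxels, max |t| = %.2f\n",
              x$label, x$effect, x$df, sum(x$mask),
              max(abs(x$t[x$mask][is.finite(x$t[x$mask])]), 0)))
  invisible(x)
}
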