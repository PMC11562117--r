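#' Table-1-style cohort summary
#'
#' Continuous variables are gated through a Shapiro-Wilk normality test
#' (alpha 0.05): normal variables are summarised as mean +/- SD, skewed ones
#' as median +/- IQR (reported as the single width Q3 - Q1), each with the
#' total range. Categorical variables are summarised as counts with
#' percentages rounded half-up to one decimal. Variables are picked up from
#' the columns present in `patients` (the [fit_d50_cohort()] schema):
#' `age_at_mri`, `t_mri_months` (symptom duration at scan), `d50`,
#' `rd50_at_mri` as continuous; `sex`, `onset_site`, `aggressiveness`,
#' `phase` as categorical.
#'
#' @param patients tibble of patient records; needs >= 3 subjects for the
#'   normality gate.
#' @param alpha Shapiro-Wilk significance level for the normality gate.
#' @return a tibble with one row per continuous variable or per categorical
#'   level: `variable`, `level`, `kind` (`continuous_normal`,
#'   `continuous_skewed` or `categorical`), `n`, `center`, `spread`, `min`,
#'   `max`, `count`, `percent`, and a formatted `label`.
#' @examples
#' coh <- simulate_cohort(n = 30, seed = 1)
#' fits <- fit_d50_cohort(coh$scores, coh$patients)
#' summarize_cohort(fits)
#' @export
summarize_cohort <- function(patients, alpha = 0.05) {
  stop_if(nrow(patients) == 0, "empty cohort")
  stop_if(nrow(patients) < 3, "need >= 3 subjects for normality testing")
  n_total <- nrow(patients)

  cont_vars <- intersect(c("age_at_mri", "t_mri_months", "d50",
                           "rd50_at_mri"), names(patients))
  cat_vars <- intersect(c("sex", "onset_site", "aggressiveness", "phase"),
                        names(patients))

  cont <- purrr::map_dfr(cont_vars, function(v) {
    x <- patients[[v]]
    x <- x[!is.na(x)]
    normal <- shapiro.test(x)$p.value >= alpha
    if (normal) {
      center <- mean(x)
      spread <- sd(x)
    } else {
      center <- median(x)
      spread <- unname(diff(quantile(x, c(0.25, 0.75))))
    }
    tibble(
      variable = v, level = NA_character_,
      kind = if (normal) "continuous_normal" else "continuous_skewed",
      n = length(x), center = center, spread = spread,
      min = min(x), max = max(x), count = NA_integer_, percent = NA_real_,
      label = sprintf("%.2f ± %.2f (%.2f–%.2f)",
                      round_half_up(center, 2), round_half_up(spread, 2),
                      round_half_up(min(x), 2), round_half_up(max(x), 2))
    )
  })

  cats <- purrr::map_dfr(cat_vars, function(v) {
    x <- factor(patients[[v]])
    tab <- table(x)
    purrr::map_dfr(names(tab), function(lv) {
      cnt <- as.integer(tab[[lv]])
      pc <- pct1(cnt, n_total)
      tibble(
        variable = v, level = lv, kind = "categorical", n = n_total,
        center = NA_real_, spread = NA_real_, min = NA_real_, max = NA_real_,
        count = cnt, percent = pc,
        label = sprintf("%d (%.1f%%)", cnt, pc)
      )
    })
  })

  dplyr::bind_rows(cont, cats)
}

#' Compare two groups with the appropriate test
#'
#' Continuous samples are gated through Shapiro-Wilk on each group (alpha
#' 0.05): both normal uses the two-sample t-test (pooled variance by
#' default), otherwise the Mann-Whitney U test. Categorical data use the
#' chi-squared test on the contingency table, without continuity correction
#' by default (the convention under which small 2x2 clinical tables
#' reproduce commonly reported p values; correction is available via
#' `correct`).
#'
#' @param a,b the two samples: numeric vectors for `continuous`; factors or
#'   character vectors for `categorical`. For `categorical`, `a` may instead
#'   be a complete contingency matrix (rows = groups) with `b` omitted.
#' @param kind `"continuous"` or `"categorical"`.
#' @param alpha Shapiro-Wilk level for the normality gate.
#' @param correct apply the continuity correction to chi-squared (default
#'   `FALSE`).
#' @param var_equal pooled-variance t-test (default `TRUE`); `FALSE` gives
#'   Welch.
#' @return a one-row tibble: `test`, `statistic`, `p_value`, and for the
#'   continuous branch `normal_a`, `normal_b`.
#' @examples
#' compare_groups(matrix(c(20, 27, 14, 55), 2), kind = "categorical")
#' @export
compare_groups <- function(a, b = NULL, kind = c("continuous", "categorical"),
                           alpha = 0.05, correct = FALSE, var_equal = TRUE) {
  kind <- match.arg(kind)
  if (kind == "categorical") {
    tab <- if (is.matrix(a)) {
      a
    } else {
      stop_if(is.null(b), "two samples (or a matrix) required")
      stop_if(length(a) == 0 || length(b) == 0, "samples must be non-empty")
      lv <- union(unique(as.character(a)), unique(as.character(b)))
      rbind(table(factor(a, levels = lv)), table(factor(b, levels = lv)))
    }
    stop_if(any(rowSums(tab) == 0) || any(colSums(tab) == 0),
            "degenerate contingency table (empty row or column)")
    ct <- suppressWarnings(chisq.test(tab, correct = correct))
    return(tibble(test = "chi-squared",
                  statistic = unname(ct$statistic),
                  p_value = ct$p.value,
                  normal_a = NA, normal_b = NA))
  }
  stop_if(is.null(b), "two samples required")
  stop_if(length(a) == 0 || length(b) == 0, "samples must be non-empty")
  sw <- function(x) {
    if (length(x) < 3 || length(unique(x)) == 1) {
      return(FALSE)
    }
    shapiro.test(x)$p.value >= alpha
  }
  na <- sw(a)
  nb <- sw(b)
  if (na && nb) {
    tt <- t.test(a, b, var.equal = var_equal)
    tibble(test = if (var_equal) "t-test" else "Welch t-test",
           statistic = unname(tt$statistic), p_value = tt$p.value,
           normal_a = na, normal_b = nb)
  } else {
    wt <- suppressWarnings(wilcox.test(a, b))
    tibble(test = "Mann-Whitney U", statistic = unname(wt$statistic),
           p_value = wt$p.value, normal_a = na, normal_b = nb)
  }
}
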