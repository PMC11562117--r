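#' Tidy a D50 fit
#'
#' @param x a [fit_d50()] result.
#' @param ... unused.
#' @return a tibble with one row per model parameter.
#' @export
tidy.d50_fit <- function(x, ...) {
  tibble(term = c("d50", "dx"), estimate = c(x$d50, x$dx))
}

#' One-row summary of a D50 fit
#'
#' @param x a [fit_d50()] result.
#' @param ... unused.
#' @return a one-row tibble.
#' @export
glance.d50_fit <- function(x, ...) {
  tibble(d50 = x$d50, dx = x$dx, rss = x$rss, n_obs = x$n_obs,
         converged = x$converged)
}

#' Tidy a voxel-wise t-map into a per-voxel table
#'
#' @param x a [fit_voxelwise_glm()] result.
#' @param ... unused.
#' @return a tibble with columns `i`, `j`, `k`, `t` over the analysis mask.
#' @export
tidy.t_map <- function(x, ...) {
  idx <- which(x$mask, arr.ind = TRUE)
  tibble(i = idx[, 1], j = idx[, 2], k = idx[, 3], t = x$t[x$mask])
}

#' One-row summary of a voxel-wise t-map
#'
#' @param x a [fit_voxelwise_glm()] result.
#' @param ... unused.
#' @return a one-row tibble.
#' @export
glance.t_map <- function(x, ...) {
  tv <- x$t[x$mask]
  tv <- tv[is.finite(tv)]
  tibble(label = x$label, effect = x$effect, df = x$df,
         n_voxels = sum(x$mask), max_t = max(tv), min_t = min(tv))
}
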