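#' @importFrom ggplot2 ggplot aes geom_point geom_line geom_raster geom_tile
#'   labs scale_fill_viridis_c scale_fill_gradient2 coord_fixed theme_minimal
#'   geom_hline geom_vline annotate
NULL

#' Plot a fitted D50 decline curve
#'
#' Observed ALSFRS-R scores with the fitted sigmoid; dashed guides mark
#' t = D50 and the half-function score of 24.
#'
#' @param object a [fit_d50()] result.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.d50_fit <- function(object, ...) {
  tmax <- max(object$data$t, 2 * object$d50) * 1.05
  curve <- tibble(t = seq(0, tmax, length.out = 200))
  curve$score <- alsfrs_sigmoid(curve$t, object$d50, object$dx)
  ggplot(object$data, aes(x = .data$t, y = .data$score)) +
    geom_line(data = curve, colour = "steelblue") +
    geom_point(size = 2) +
    geom_vline(xintercept = object$d50, linetype = "dashed",
               colour = "grey40") +
    geom_hline(yintercept = 24, linetype = "dashed", colour = "grey40") +
    labs(x = "Months since symptom onset", y = "ALSFRS-R",
         title = sprintf("D50 = %.1f months, dx = %.1f", object$d50,
                         object$dx)) +
    theme_minimal()
}

slice_tibble <- function(arr, slice, axis) {
  d <- dim(arr)
  ax <- match(axis, c("sagittal", "coronal", "axial")) # fixes dim 1/2/3
  if (is.null(slice)) slice <- ceiling(d[ax] / 2)
  sl <- switch(ax, arr[slice, , ], arr[, slice, ], arr[, , slice])
  g <- expand.grid(u = seq_len(nrow(sl)), v = seq_len(ncol(sl)))
  g$value <- as.vector(sl)
  g
}

#' Plot one slice of a texture map
#'
#' @param object a [texture_map()] result.
#' @param slice slice index (defaults to the middle slice).
#' @param axis `"axial"` (fixes z), `"coronal"` (fixes y) or `"sagittal"`
#'   (fixes x).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.texture_map <- function(object, slice = NULL, axis = "axial", ...) {
  g <- slice_tibble(object$data, slice, axis)
  ggplot(g, aes(x = .data$u, y = .data$v, fill = .data$value)) +
    geom_raster() +
    scale_fill_viridis_c(na.value = "grey90", name = "autocorr") +
    coord_fixed() +
    labs(x = NULL, y = NULL, title = sprintf("GLCM autocorrelation (%s)",
                                             axis)) +
    theme_minimal()
}

#' Plot one slice of a t-map
#'
#' @param object a [fit_voxelwise_glm()] result.
#' @param slice slice index (defaults to the middle slice).
#' @param axis `"axial"`, `"coronal"` or `"sagittal"`.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.t_map <- function(object, slice = NULL, axis = "axial", ...) {
  g <- slice_tibble(object$t, slice, axis)
  ggplot(g, aes(x = .data$u, y = .data$v, fill = .data$value)) +
    geom_raster() +
    scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick",
                         na.value = "grey90", name = "t") +
    coord_fixed() +
    labs(x = NULL, y = NULL,
         title = sprintf("%s (df = %d, %s)", object$label, object$df,
                         axis)) +
    theme_minimal()
}
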