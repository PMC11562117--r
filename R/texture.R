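#' Quantize a masked volume to grey levels
#'
#' Global min-max linear quantization over the masked voxels:
#' `level = min(floor((v - vmin) / (vmax - vmin) * ng) + 1, ng)`. A constant
#' volume (vmin == vmax) maps to level 1 everywhere inside the mask. Voxels
#' outside the mask get level 0. Because the binning is min-max based, the
#' levels — and everything derived from them — are invariant under any
#' positive affine rescaling of the intensities.
#'
#' @param vol a [masked_volume()].
#' @param n_levels number of grey levels Ng (>= 2); 8 by default.
#' @return an object of class `quantized_volume` with fields `levels`
#'   (integer 3D array), `n_levels` and `mask`.
#' @export
quantize_volume <- function(vol, n_levels = 8) {
  stop_if(!inherits(vol, "masked_volume"), "`vol` must be a masked_volume")
  stop_if(n_levels < 2, "`n_levels` must be >= 2")
  v <- vol$data[vol$mask]
  stop_if(anyNA(v), "masked voxels contain NA intensities")
  vmin <- min(v)
  vmax <- max(v)
  lev <- array(0L, dim(vol$data))
  if (vmax > vmin) {
    l <- floor((vol$data[vol$mask] - vmin) / (vmax - vmin) * n_levels) + 1
    lev[vol$mask] <- as.integer(pmin(l, n_levels))
  } else {
    lev[vol$mask] <- 1L
  }
  structure(
    list(levels = lev, n_levels = as.integer(n_levels), mask = vol$mask),
    class = "quantized_volume"
  )
}

#' GLCM for one voxel's in-plane neighbourhood
#'
#' Accumulates symmetric grey-level co-occurrences over all four in-plane
#' directions (0, 45, 90, 135 degrees) at the given distance, between voxel
#' pairs whose members both lie inside the `(2 * radius + 1)^2` in-plane
#' window centred on `center` and inside the mask. Each unordered pair is
#' counted in both orientations, so the matrix is symmetric. With no valid
#' pair the matrix is all-zero and `pair_count` is 0.
#'
#' @param qvol a [quantize_volume()] result.
#' @param center integer length-3 voxel index (1-based); must be in-mask.
#' @param plane `"axial"` (x,y), `"coronal"` (x,z) or `"sagittal"` (y,z) in
#'   grid axes.
#' @param radius in-plane window radius in voxels (>= 1).
#' @param distance co-occurrence offset in voxels (>= 1).
#' @return an object of class `glcm`: `p` (Ng x Ng probability matrix,
#'   summing to 1 when pairs exist) and `pair_count`.
#' @export
glcm_window <- function(qvol, center, plane = c("axial", "coronal", "sagittal"),
                        radius = 1, distance = 1) {
  plane <- match.arg(plane)
  stop_if(radius < 1 || distance < 1, "`radius` and `distance` must be >= 1")
  center <- as.integer(center)
  stop_if(length(center) != 3, "`center` must be a length-3 voxel index")
  stop_if(!qvol$mask[center[1], center[2], center[3]],
          "`center` lies outside the mask")
  axes <- switch(plane, axial = c(1L, 2L), coronal = c(1L, 3L),
                 sagittal = c(2L, 3L))
  dims <- dim(qvol$levels)
  ng <- qvol$n_levels
  dirs <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1)) * distance
  counts <- matrix(0, ng, ng)
  for (a in -radius:radius) {
    for (b in -radius:radius) {
      q1 <- center
      q1[axes] <- q1[axes] + c(a, b)
      if (any(q1 < 1L) || any(q1 > dims)) next
      l1 <- qvol$levels[q1[1], q1[2], q1[3]]
      if (l1 == 0L) next
      for (d in seq_len(nrow(dirs))) {
        ab2 <- c(a, b) + dirs[d, ]
        if (any(abs(ab2) > radius)) next
        q2 <- center
        q2[axes] <- q2[axes] + ab2
        if (any(q2 < 1L) || any(q2 > dims)) next
        l2 <- qvol$levels[q2[1], q2[2], q2[3]]
        if (l2 == 0L) next
        counts[l1, l2] <- counts[l1, l2] + 1
        counts[l2, l1] <- counts[l2, l1] + 1
      }
    }
  }
  n <- sum(counts)
  structure(
    list(p = if (n > 0) counts / n else counts, pair_count = n),
    class = "glcm"
  )
}

#' Autocorrelation of a normalized GLCM
#'
#' The Haralick-family autocorrelation feature
#' `sum_i sum_j i * j * p(i, j)` with levels indexed 1..Ng. High values mean
#' co-occurring levels are jointly high, i.e. strong positive neighbour
#' correlation of bright voxels. An empty matrix (`pair_count` 0) returns
#' `NA`.
#'
#' @param glcm a [glcm_window()] result, or a bare normalized matrix.
#' @return scalar in `[1, Ng^2]`, or `NA` when no pairs were accumulated.
#' @export
glcm_autocorrelation <- function(glcm) {
  p <- if (inherits(glcm, "glcm")) glcm$p else glcm
  stop_if(any(p < 0), "GLCM entries must be non-negative")
  if (sum(p) == 0) {
    return(NA_real_)
  }
  ng <- nrow(p)
  idx <- seq_len(ng)
  sum(outer(idx, idx) * p)
}

#' Voxel-wise GLCM autocorrelation map on three orthogonal planes
#'
#' For every masked voxel, one GLCM is computed per orthogonal plane through
#' the voxel ([glcm_window()] semantics), the autocorrelation feature is
#' evaluated for each plane with at least one valid pair, and the mean over
#' valid planes is stored. Voxels with no valid pair in any plane are `NA`
#' and are dropped from downstream statistics. No spatial smoothing is
#' applied to the map (smoothing kernel 0).
#'
#' @param vol a [masked_volume()].
#' @param radius in-plane window radius in voxels; default 1.
#' @param distance co-occurrence distance in voxels; default 1.
#' @param n_levels quantization level count Ng; default 8.
#' @param per_window if `TRUE`, quantization is min-max within each in-plane
#'   window instead of global over the mask (off by default: inputs are
#'   assumed globally intensity-standardised upstream, and a global scale
#'   keeps the map comparable across voxels).
#' @return an object of class `texture_map`: `data` (3D array, `NA` outside
#'   mask/invalid voxels), `mask` (defined voxels), `params`, plus the source
#'   `voxel_size` and `affine`.
#' @examples
#' v <- masked_volume(array(rnorm(5^3), c(5, 5, 5)))
#' tm <- texture_map(v)
#' range(tm$data[tm$mask])
#' @export
texture_map <- function(vol, radius = 1, distance = 1, n_levels = 8,
                        per_window = FALSE) {
  stop_if(!inherits(vol, "masked_volume"), "`vol` must be a masked_volume")
  stop_if(radius < 1 || distance < 1, "`radius` and `distance` must be >= 1")
  q <- quantize_volume(vol, n_levels)
  vals <- texture_map_cpp(as.numeric(vol$data), as.logical(vol$mask),
                          as.integer(q$levels), dim(vol$data),
                          as.integer(n_levels), as.integer(radius),
                          as.integer(distance), isTRUE(per_window))
  dim(vals) <- dim(vol$data)
  structure(
    list(data = vals, mask = !is.na(vals),
         params = list(radius = radius, distance = distance,
                       n_levels = n_levels, per_window = isTRUE(per_window),
                       planes = c(axial = "xy", coronal = "xz",
                                  sagittal = "yz")),
         voxel_size = vol$voxel_size, affine = vol$affine),
    class = c("texture_map", "masked_volume")
  )
}

#' @export
print.texture_map <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf(
    "<texture_map> %d x %d x %d, %d defined voxels, Ng = %d, radius %d, distance %d\n",
    d[1], d[2], d[3], sum(x$mask), x$params$n_levels, x$params$radius,
    x$params$distance))
  invisible(x)
}
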