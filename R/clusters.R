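#' Threshold a t-map and extract supra-threshold clusters
#'
#' Converts the voxel-level probability threshold to a one-sided t cut-off
#' using the t distribution at the map's residual degrees of freedom,
#' binarizes `t > cutoff`, labels connected components at the requested
#' connectivity, and keeps clusters at least `extent` voxels large (the
#' comparator is configurable: some reports phrase the rule as "> extent").
#' One-sided thresholding matches directional contrasts; run the negated
#' contrast for the opposite direction.
#'
#' @param tmap a [fit_voxelwise_glm()] result.
#' @param p_threshold voxel-level one-sided p threshold in (0, 0.5];
#'   default 0.0005.
#' @param extent cluster extent threshold in voxels; default 10.
#' @param connectivity 6, 18 or 26 neighbourhood (default 18, the common
#'   cluster-forming convention in SPM).
#' @param extent_comparator `"ge"` keeps clusters with size >= extent
#'   (default); `"gt"` keeps size > extent.
#' @return a tibble of class `cluster_table`, sorted by size then peak t
#'   then lexicographic peak index, with columns `cluster_id`, `size_vox`,
#'   `peak_t`, `peak_i/j/k` (1-based grid) and `peak_x/y/z_mm` (world via
#'   the affine). Attributes: `t_cutoff`, `df`, `p_threshold`, `extent`,
#'   `connectivity`, `label`, and `label_array` (the full cluster-label
#'   grid, retained clusters only).
#' @examples
#' # an empty map yields an empty table
#' @export
threshold_clusters <- function(tmap, p_threshold = 0.0005, extent = 10,
                               connectivity = c(18, 6, 26),
                               extent_comparator = c("ge", "gt")) {
  stop_if(!inherits(tmap, "t_map"), "`tmap` must be a t_map")
  stop_if(p_threshold <= 0 || p_threshold > 0.5,
          "`p_threshold` must lie in (0, 0.5]")
  connectivity <- match.arg(as.character(connectivity[1]),
                            c("18", "6", "26"))
  connectivity <- as.integer(connectivity)
  extent_comparator <- match.arg(extent_comparator)

  cutoff <- qt(1 - p_threshold, df = tmap$df)
  supra <- !is.na(tmap$t) & tmap$t > cutoff
  empty <- tibble(
    cluster_id = integer(), size_vox = integer(), peak_t = numeric(),
    peak_i = integer(), peak_j = integer(), peak_k = integer(),
    peak_x_mm = numeric(), peak_y_mm = numeric(), peak_z_mm = numeric()
  )
  finish <- function(tbl, labels) {
    structure(tbl, class = c("cluster_table", class(tbl)),
              t_cutoff = cutoff, df = tmap$df, p_threshold = p_threshold,
              extent = extent, connectivity = connectivity,
              label = tmap$label, label_array = labels)
  }
  if (!any(supra)) {
    return(finish(empty, array(0L, dim(tmap$t))))
  }

  lab <- label_components_cpp(as.logical(supra), dim(tmap$t), connectivity)
  sizes <- tabulate(lab[lab > 0])
  keep_ids <- which(if (extent_comparator == "ge") sizes >= extent
                    else sizes > extent)
  out_lab <- array(0L, dim(tmap$t))
  if (length(keep_ids) == 0) {
    return(finish(empty, out_lab))
  }

  rows <- purrr::map_dfr(keep_ids, function(id) {
    vox <- which(lab == id, arr.ind = TRUE)
    tv <- tmap$t[lab == id]
    # peak: max t, ties to the lexicographically smallest index
    o <- order(-tv, vox[, 1], vox[, 2], vox[, 3])
    pk <- vox[o[1], ]
    tibble(size_vox = nrow(vox), peak_t = tv[o[1]],
           peak_i = pk[1], peak_j = pk[2], peak_k = pk[3])
  })
  o <- order(-rows$size_vox, -rows$peak_t, rows$peak_i, rows$peak_j,
             rows$peak_k)
  rows <- rows[o, ]
  kept <- keep_ids[o]
  for (r in seq_along(kept)) {
    out_lab[lab == kept[r]] <- r
  }
  world <- voxel_to_world(cbind(rows$peak_i, rows$peak_j, rows$peak_k),
                          tmap$affine)
  tbl <- tibble(
    cluster_id = seq_len(nrow(rows)), size_vox = as.integer(rows$size_vox),
    peak_t = rows$peak_t,
    peak_i = as.integer(rows$peak_i), peak_j = as.integer(rows$peak_j),
    peak_k = as.integer(rows$peak_k),
    peak_x_mm = world[, 1], peak_y_mm = world[, 2], peak_z_mm = world[, 3]
  )
  finish(tbl, out_lab)
}

#' Dice overlap between a cluster and a reference region
#'
#' `2 |A & B| / (|A| + |B|)` between the member voxels of one cluster of a
#' [threshold_clusters()] table and a logical reference array (e.g. the true
#' ROI of a phantom study).
#'
#' @param clusters a `cluster_table`.
#' @param reference logical 3D array.
#' @param cluster_id which cluster (default 1, the largest).
#' @return Dice coefficient in `[0, 1]`; 0 when the table is empty.
#' @export
cluster_dice <- function(clusters, reference, cluster_id = 1) {
  lab <- attr(clusters, "label_array")
  if (nrow(clusters) < cluster_id) {
    return(0)
  }
  a <- lab == cluster_id
  2 * sum(a & reference) / (sum(a) + sum(reference))
}
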