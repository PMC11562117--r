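#' Masked 3D volume
#'
#' A minimal container for a scalar 3D image on a regular grid together with
#' a boolean analysis mask, the voxel size in mm, and a 4x4 grid-to-world
#' affine (NIfTI convention: 0-based voxel indices map to world mm).
#'
#' @param data numeric 3D array.
#' @param mask logical 3D array of the same shape, or `NULL` for all-true.
#' @param voxel_size numeric length-3, mm per axis.
#' @param affine 4x4 grid-to-world matrix; defaults to a diagonal scaling by
#'   `voxel_size`.
#' @return an object of class `masked_volume`.
#' @examples
#' v <- masked_volume(array(rnorm(27), c(3, 3, 3)))
#' dim(v$data)
#' @export
masked_volume <- function(data, mask = NULL, voxel_size = c(1, 1, 1),
                          affine = NULL) {
  stop_if(!is.array(data) || length(dim(data)) != 3L,
          "`data` must be a 3D array")
  if (is.null(mask)) {
    mask <- array(TRUE, dim(data))
  }
  storage.mode(mask) <- "logical"
  stop_if(!identical(dim(mask), dim(data)),
          "`mask` and `data` shapes differ")
  stop_if(!any(mask), "mask has no included voxels")
  stop_if(any(voxel_size <= 0), "`voxel_size` must be positive")
  if (is.null(affine)) {
    affine <- diag(c(voxel_size, 1))
  }
  stop_if(!identical(dim(affine), c(4L, 4L)), "`affine` must be 4x4")
  structure(
    list(data = data, mask = mask, voxel_size = as.numeric(voxel_size),
         affine = affine),
    class = "masked_volume"
  )
}

#' @export
print.masked_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<masked_volume> %d x %d x %d, %d masked voxels, voxel %s mm\n",
              d[1], d[2], d[3], sum(x$mask),
              paste(signif(x$voxel_size, 3), collapse = " x ")))
  invisible(x)
}

#' Read a NIfTI volume (with optional mask) into a `masked_volume`
#'
#' @param path NIfTI-1 image (.nii or .nii.gz).
#' @param mask_path optional NIfTI mask; nonzero voxels are included. When
#'   omitted the whole grid is analysed.
#' @return a [masked_volume()].
#' @export
read_volume <- function(path, mask_path = NULL) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim(img)[1:3])
  mask <- NULL
  if (!is.null(mask_path)) {
    m <- RNifti::readNifti(mask_path)
    stop_if(!identical(dim(m)[1:3], dim(arr)),
            "mask grid does not match image grid")
    mask <- array(as.numeric(m) != 0, dim(arr))
  }
  af <- matrix(as.numeric(RNifti::xform(img)), 4, 4)
  masked_volume(arr, mask,
                voxel_size = sqrt(colSums(af[1:3, 1:3]^2)),
                affine = af)
}

#' Write a volume (or bare array) as NIfTI-1
#'
#' Data are written as float32 with the volume's affine; `NA` values are
#' written as 0 (the mask distinguishes them downstream).
#'
#' @param vol a [masked_volume()], `texture_map`, `t_map`, or 3D array.
#' @param path output .nii or .nii.gz path.
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  if (is.array(vol)) {
    vol <- masked_volume(vol)
  }
  arr <- if (!is.null(vol$data)) vol$data else vol$t
  arr[is.na(arr)] <- 0
  img <- RNifti::asNifti(arr, datatype = "float")
  img <- RNifti::`sform<-`(img, structure(vol$affine, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

# 1-based grid index matrix (n x 3) -> world mm via the affine
voxel_to_world <- function(ijk, affine) {
  ijk <- matrix(ijk, ncol = 3)
  h <- cbind(ijk - 1, 1) %*% t(affine)
  h[, 1:3, drop = FALSE]
}
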