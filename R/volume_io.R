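#' Masked 3D volume
#'
#' Bundles a 3D intensity grid with a binary brain mask of the same shape.
#' The mask marks the voxels that enter all statistics: intensity
#' normalisation and the reconstruction loss both ignore background voxels,
#' which are held at exactly zero (the convention of brain-extracted,
#' linearly registered images).
#'
#' @param intensities 3D numeric array.
#' @param mask Optional logical array of the same shape. Defaults to
#'   `intensities != 0`.
#' @param affine Optional 4x4 voxel-to-world matrix, carried through I/O but
#'   never used for resampling (inputs are assumed pre-registered).
#' @return An object of class `masked_volume`.
#' @export
masked_volume <- function(intensities, mask = NULL, affine = NULL) {
  if (!is.array(intensities) || length(dim(intensities)) != 3L)
    stop("`intensities` must be a 3D array, got ",
         length(dim(intensities)), " dimensions")
  if (is.null(mask)) mask <- intensities != 0
  if (!identical(dim(mask), dim(intensities)))
    stop("mask shape ", paste(dim(mask), collapse = "x"),
         " does not match intensity shape ",
         paste(dim(intensities), collapse = "x"))
  structure(list(intensities = intensities, mask = array(as.logical(mask),
                                                         dim(intensities)),
                 affine = affine),
            class = "masked_volume")
}

#' @export
print.masked_volume <- function(x, ...) {
  cat("masked_volume", paste(dim(x$intensities), collapse = " x "),
      sprintf("(%d masked voxels, %.1f%% of grid)\n", sum(x$mask),
              100 * mean(x$mask)))
  invisible(x)
}

#' Read a 3D NIfTI volume
#'
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @param mask_threshold Absolute intensity at or below which a voxel counts
#'   as background. The default 0 reproduces the exact-zero background of
#'   brain-extracted images.
#' @return A [masked_volume].
#' @export
read_volume <- function(path, mask_threshold = 0) {
  if (!file.exists(path)) stop("cannot read volume: no such file: ", path)
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3L)
    stop("expected a 3D volume, got a ", length(d), "D image: ", path)
  arr <- array(as.numeric(img), d)
  masked_volume(arr, mask = abs(arr) > mask_threshold,
                affine = structure(RNifti::xform(img), code = NULL))
}

#' Write a volume as NIfTI
#'
#' @param vol A [masked_volume] or a 3D array.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path) {
  arr <- if (inherits(vol, "masked_volume")) vol$intensities else vol
  if (!is.array(arr) || length(dim(arr)) != 3L)
    stop("`vol` must be a 3D array or masked_volume")
  RNifti::writeNifti(RNifti::asNifti(arr), path)
  invisible(path)
}

#' Derive the brain mask from a volume
#'
#' The mask is the step function of the image: every voxel whose intensity
#' differs from the background value (exactly zero by default) is brain.
#'
#' @param vol A [masked_volume] or 3D array.
#' @param threshold Absolute intensity at or below which a voxel is
#'   background.
#' @return A logical 3D array.
#' @export
compute_mask <- function(vol, threshold = 0) {
  arr <- if (inherits(vol, "masked_volume")) vol$intensities else vol
  m <- abs(arr) > threshold
  if (!any(m)) stop("all-zero volume: no brain voxels above threshold")
  m
}

#' Background-excluded z-score normalisation
#'
#' Centres and scales the masked voxels to mean 0 and (population) standard
#' deviation 1; background voxels stay exactly 0. Excluding the background
#' from the statistics prevents the large zero region from skewing them.
#' The operation is idempotent and invariant to positive affine rescaling of
#' the masked intensities.
#'
#' @param vol A [masked_volume].
#' @return A [masked_volume] with normalised intensities.
#' @export
znormalize <- function(vol) {
  stopifnot(inherits(vol, "masked_volume"))
  v <- vol$intensities[vol$mask]
  mu <- mean(v)
  s <- sqrt(mean((v - mu)^2))
  if (!is.finite(s) || s < 1e-12)
    stop("masked intensities are constant (sd = 0); cannot z-normalise")
  out <- array(0, dim(vol$intensities))
  out[vol$mask] <- (v - mu) / s
  masked_volume(out, mask = vol$mask, affine = vol$affine)
}
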