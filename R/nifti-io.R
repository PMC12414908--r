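#' Read a 3-D volume from a NIfTI-1 file
#'
#' Loads voxel values and geometry (spacing, origin, direction) from the
#' NIfTI affine. Values must be finite and the image 3-D.
#'
#' @param path path to a `.nii` or `.nii.gz` file.
#' @return a [volume_grid].
#' @seealso [write_volume]
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("volume file not found: ", path)
  img <- RNifti::readNifti(path)
  vals <- as.array(img)
  if (length(dim(vals)) != 3L)
    stop("expected a 3-D image, got ", length(dim(vals)), "-D: ", path)
  vals <- array(as.numeric(vals), dim(vals))  # strip niftiImage attributes
  if (any(!is.finite(vals)))
    stop("volume contains non-finite voxels: ", path)
  aff <- unclass(RNifti::xform(img, useQuaternionFirst = FALSE))
  aff <- matrix(as.numeric(aff[1:4, 1:4]), 4, 4)
  spacing <- sqrt(colSums(aff[1:3, 1:3]^2))
  if (any(spacing <= 0)) stop("degenerate affine (zero spacing): ", path)
  direction <- sweep(aff[1:3, 1:3], 2, spacing, "/")
  volume_grid(vals, spacing = spacing, origin = aff[1:3, 4],
              direction = direction)
}

#' Write a volume to a NIfTI-1 file
#'
#' Stores the grid geometry in the sform (code 2) and pixdim so that
#' [read_volume] recovers values bit-exactly and geometry to better than
#' 1e-6 mm.
#'
#' @param grid a [volume_grid].
#' @param path destination path (`.nii` or `.nii.gz`); the parent directory
#'   must exist.
#' @return `path`, invisibly.
#' @export
write_volume <- function(grid, path) {
  stopifnot(inherits(grid, "volume_grid"))
  if (!dir.exists(dirname(path)))
    stop("parent directory does not exist: ", dirname(path))
  img <- RNifti::asNifti(grid$values)
  RNifti::pixdim(img) <- grid$spacing
  aff <- grid_affine(grid)
  img <- RNifti::`sform<-`(img, structure(aff, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}
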