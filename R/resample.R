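#' Resample a volume into a reference geometry through an affine transform
#'
#' Pull-based resampling: each voxel centre of the reference grid is mapped
#' through the inverse of `transform` into the source world space, converted
#' to a continuous source voxel index, and interpolated. This is the step
#' that carries maps between image spaces (e.g. applying the inverse of a
#' CT registration matrix to move MRI-derived maps into planning-CT space).
#'
#' `transform` maps source world coordinates (mm) to reference world
#' coordinates. Voxels whose pre-image falls outside the source domain get
#' `fill` (default 0: contributes no dose and no cells). Use
#' `interpolation = "nearest"` for binary masks and `"linear"` (trilinear)
#' for scalar maps.
#'
#' @param grid source [volume_grid].
#' @param transform an [affine_transform] from source world space to
#'   reference world space; `NULL` means identity.
#' @param reference a [volume_grid] supplying the output geometry (its
#'   values are ignored).
#' @param interpolation `"nearest"` or `"linear"`.
#' @param fill value for voxels mapping outside the source domain.
#' @return a [volume_grid] with the reference geometry.
#' @export
resample_to <- function(grid, transform = NULL, reference,
                        interpolation = c("nearest", "linear"),
                        fill = 0) {
  stopifnot(inherits(grid, "volume_grid"), inherits(reference, "volume_grid"))
  interpolation <- match.arg(interpolation)
  if (is.null(transform)) transform <- affine_transform(diag(4))
  stopifnot(inherits(transform, "affine_transform"))

  dm <- dim(reference$values)
  n <- prod(dm)
  # 0-based output voxel indices, one row per voxel
  idx <- arrayInd(seq_len(n), dm) - 1L
  # output voxel centres in world mm
  world <- t(reference$direction %*% (t(idx) * reference$spacing)) +
    rep(reference$origin, each = n)
  # pull back into source world space, then to continuous source indices
  inv <- solve(transform$matrix)
  src_world <- world %*% t(inv[1:3, 1:3]) + rep(inv[1:3, 4], each = n)
  cont <- (src_world - rep(grid$origin, each = n)) %*% grid$direction
  cont <- sweep(cont, 2, grid$spacing, "/")

  sdm <- dim(grid$values)
  out <- if (interpolation == "nearest") {
    near <- round(cont)
    inside <- near[, 1] >= 0 & near[, 1] <= sdm[1] - 1 &
      near[, 2] >= 0 & near[, 2] <= sdm[2] - 1 &
      near[, 3] >= 0 & near[, 3] <= sdm[3] - 1
    v <- rep(fill, n)
    v[inside] <- grid$values[near[inside, , drop = FALSE] + 1L]
    v
  } else {
    lo <- floor(cont)
    fr <- cont - lo
    inside <- lo[, 1] >= -1 & lo[, 1] <= sdm[1] - 1 &
      lo[, 2] >= -1 & lo[, 2] <= sdm[2] - 1 &
      lo[, 3] >= -1 & lo[, 3] <= sdm[3] - 1
    v <- rep(fill, n)
    if (any(inside)) {
      loi <- lo[inside, , drop = FALSE]
      fri <- fr[inside, , drop = FALSE]
      acc <- numeric(sum(inside))
      for (dx in 0:1) for (dy in 0:1) for (dz in 0:1) {
        w <- (if (dx) fri[, 1] else 1 - fri[, 1]) *
          (if (dy) fri[, 2] else 1 - fri[, 2]) *
          (if (dz) fri[, 3] else 1 - fri[, 3])
        cx <- loi[, 1] + dx; cy <- loi[, 2] + dy; cz <- loi[, 3] + dz
        ok <- cx >= 0 & cx <= sdm[1] - 1 & cy >= 0 & cy <= sdm[2] - 1 &
          cz >= 0 & cz <= sdm[3] - 1
        val <- rep(fill, length(w))
        if (any(ok))
          val[ok] <- grid$values[cbind(cx[ok], cy[ok], cz[ok]) + 1L]
        acc <- acc + w * val
      }
      v[inside] <- acc
    }
    v
  }
  volume_grid(array(out, dm), spacing = reference$spacing,
              origin = reference$origin, direction = reference$direction)
}

#' Resample a binary mask, re-binarising the result
#'
#' Nearest-neighbour resampling already yields {0,1}; after linear
#' resampling the mask is thresholded at 0.5 (standard mask-resampling
#' convention).
#'
#' @inheritParams resample_to
#' @return a binary [volume_grid] with the reference geometry.
#' @export
resample_mask <- function(grid, transform = NULL, reference,
                          interpolation = c("nearest", "linear")) {
  interpolation <- match.arg(interpolation)
  out <- resample_to(grid, transform, reference, interpolation, fill = 0)
  if (interpolation == "linear")
    out <- with_values(out, as.numeric(out$values >= 0.5))
  out
}
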