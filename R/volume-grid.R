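#' Construct a voxel grid
#'
#' A `volume_grid` is the common substrate for every scalar field in the
#' package: cellularity (cells/voxel or cells/mm^3), RBE-weighted dose in
#' Gy(RBE), binary masks, or dimensionless per-voxel scores. It couples a 3-D
#' numeric array with its physical geometry: voxel spacing in mm, the world
#' coordinate (mm) of the centre of voxel (0,0,0), and a 3x3 orthonormal
#' direction matrix. World position of 0-based voxel index `(i,j,k)` is
#' `direction %*% (c(i,j,k) * spacing) + origin` (voxel-centre convention,
#' matching NIfTI affine semantics).
#'
#' @param values 3-D numeric array of voxel values; must be finite.
#' @param spacing numeric(3), strictly positive voxel spacing in mm.
#' @param origin numeric(3), world coordinates (mm) of the centre of the
#'   voxel with 0-based index (0,0,0).
#' @param direction 3x3 orthonormal orientation matrix (columns are the
#'   world directions of the voxel axes).
#' @return An object of class `volume_grid`.
#' @examples
#' g <- volume_grid(array(0, c(4, 4, 4)), spacing = c(2, 2, 2))
#' voxel_volume(g)  # 8 mm^3
#' @export
volume_grid <- function(values,
                        spacing = c(1, 1, 1),
                        origin = c(0, 0, 0),
                        direction = diag(3)) {
  if (!is.array(values) || length(dim(values)) != 3L)
    stop("'values' must be a 3-D array, got dimensions: ",
         paste(dim(values), collapse = "x"))
  storage.mode(values) <- "double"
  if (any(!is.finite(values)))
    stop("'values' contains ", sum(!is.finite(values)),
         " non-finite voxel(s); volume grids must be finite")
  spacing <- as.numeric(spacing)
  origin <- as.numeric(origin)
  if (length(spacing) != 3L || any(!is.finite(spacing)) || any(spacing <= 0))
    stop("'spacing' must be 3 strictly positive values (mm)")
  if (length(origin) != 3L || any(!is.finite(origin)))
    stop("'origin' must be 3 finite values (mm)")
  direction <- as.matrix(direction)
  if (!all(dim(direction) == c(3L, 3L)))
    stop("'direction' must be a 3x3 matrix")
  if (max(abs(crossprod(direction) - diag(3))) > 1e-6)
    stop("'direction' must be orthonormal (within 1e-6)")
  structure(
    list(values = values, spacing = spacing, origin = origin,
         direction = direction),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("<volume_grid> ", paste(dim(x$values), collapse = " x "),
      " voxels @ ", paste(format(x$spacing), collapse = " x "), " mm\n",
      sep = "")
  cat("  origin (mm): ", paste(format(x$origin), collapse = ", "), "\n",
      sep = "")
  rng <- range(x$values)
  cat("  values in [", format(rng[1]), ", ", format(rng[2]), "]\n", sep = "")
  invisible(x)
}

#' @export
dim.volume_grid <- function(x) dim(x$values)

#' Voxel volume in mm^3
#'
#' Product of the grid spacings. Used to convert cell densities (cells/mm^3)
#' to per-voxel cell counts.
#'
#' @param grid a `volume_grid`.
#' @return scalar voxel volume in mm^3.
#' @export
voxel_volume <- function(grid) {
  stopifnot(inherits(grid, "volume_grid"))
  prod(grid$spacing)
}

#' Voxel-index to world affine of a grid
#'
#' Returns the 4x4 homogeneous matrix mapping 0-based voxel indices to world
#' coordinates in mm (NIfTI sform convention).
#'
#' @param grid a `volume_grid`.
#' @return 4x4 numeric matrix.
#' @export
grid_affine <- function(grid) {
  stopifnot(inherits(grid, "volume_grid"))
  aff <- diag(4)
  aff[1:3, 1:3] <- grid$direction %*% diag(grid$spacing)
  aff[1:3, 4] <- grid$origin
  aff
}

#' Do two grids share the same geometry?
#'
#' @param a,b `volume_grid` objects.
#' @param tol geometric tolerance in mm.
#' @return logical scalar.
#' @export
same_geometry <- function(a, b, tol = 1e-6) {
  all(dim(a$values) == dim(b$values)) &&
    max(abs(a$spacing - b$spacing)) <= tol &&
    max(abs(a$origin - b$origin)) <= tol &&
    max(abs(a$direction - b$direction)) <= tol
}

#' Replace the values of a grid, keeping its geometry
#'
#' @param grid a `volume_grid` supplying the geometry.
#' @param values replacement array (same dimensions).
#' @return a new `volume_grid`.
#' @export
with_values <- function(grid, values) {
  if (!all(dim(values) == dim(grid$values)))
    stop("replacement values have different dimensions")
  volume_grid(array(values, dim(grid$values)),
              spacing = grid$spacing, origin = grid$origin,
              direction = grid$direction)
}

# internal: stop unless grids are congruent
check_congruent <- function(..., what = "grids") {
  gs <- list(...)
  for (i in seq_along(gs)[-1]) {
    if (!same_geometry(gs[[1]], gs[[i]]))
      stop(what, " must share one geometry (shape/spacing/origin/direction)")
  }
  invisible(TRUE)
}
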