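#' Construct a world-to-world affine transform
#'
#' A 4x4 homogeneous matrix mapping world coordinates (mm) of one image
#' space into another, e.g. the registration transform between diffusion-MRI
#' space and planning-CT space. The last row must be (0,0,0,1) and the upper
#' 3x3 block invertible.
#'
#' @param matrix 4x4 numeric homogeneous matrix.
#' @return An object of class `affine_transform`.
#' @examples
#' affine_transform(diag(4))             # identity
#' affine_translation(c(2, 0, 0))        # 2 mm shift along x
#' @export
affine_transform <- function(matrix) {
  m <- as.matrix(matrix)
  if (!all(dim(m) == c(4L, 4L)) || any(!is.finite(m)))
    stop("an affine transform is a finite 4x4 matrix")
  if (max(abs(m[4, ] - c(0, 0, 0, 1))) > 1e-12)
    stop("last row of an affine transform must be (0, 0, 0, 1)")
  if (abs(det(m[1:3, 1:3])) <= 1e-12)
    stop("affine transform is singular (|det| of the 3x3 block <= 1e-12)")
  structure(list(matrix = m), class = "affine_transform")
}

#' @rdname affine_transform
#' @param offset numeric(3) translation in mm.
#' @export
affine_translation <- function(offset) {
  m <- diag(4)
  m[1:3, 4] <- as.numeric(offset)
  affine_transform(m)
}

#' Invert an affine transform
#'
#' @param transform an `affine_transform`.
#' @return the inverse `affine_transform`.
#' @export
affine_inverse <- function(transform) {
  stopifnot(inherits(transform, "affine_transform"))
  affine_transform(solve(transform$matrix))
}

#' Read/write an affine transform as JSON
#'
#' The matrix is stored row-major as a flat list of 16 numbers under the key
#' `"matrix"`, a plain-text interchange format for registration matrices.
#'
#' @param path file path.
#' @return `read_affine` returns an `affine_transform`; `write_affine`
#'   returns `path` invisibly.
#' @export
read_affine <- function(path) {
  if (!file.exists(path)) stop("affine file not found: ", path)
  x <- jsonlite::fromJSON(path)
  if (is.null(x$matrix) || length(unlist(x$matrix)) != 16L)
    stop("affine JSON must contain a 16-element 'matrix' (row-major)")
  affine_transform(matrix(as.numeric(unlist(x$matrix)), 4, 4, byrow = TRUE))
}

#' @rdname read_affine
#' @param transform an `affine_transform`.
#' @export
write_affine <- function(transform, path) {
  stopifnot(inherits(transform, "affine_transform"))
  jsonlite::write_json(
    list(matrix = as.numeric(t(transform$matrix))),
    path, auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

#' @export
print.affine_transform <- function(x, ...) {
  cat("<affine_transform>\n")
  print(x$matrix)
  invisible(x)
}
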