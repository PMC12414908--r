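#' Construct a structure set
#'
#' Named binary masks (regions of interest) sharing one grid geometry, with
#' a role for each: `"GTV"` (gross tumour volume), `"CTV"` (clinical target
#' volume = GTV plus a safety margin), or `"OAR"` (organ at risk). The set
#' must contain exactly one GTV and one CTV, and every GTV voxel must also
#' be a CTV voxel.
#'
#' @param masks named list of binary [volume_grid]s on a common geometry.
#' @param roles named character vector mapping mask names to
#'   `"GTV"`/`"CTV"`/`"OAR"`.
#' @return an object of class `structure_set`.
#' @export
structure_set <- function(masks, roles) {
  if (length(masks) == 0 || is.null(names(masks)))
    stop("'masks' must be a non-empty named list")
  if (!all(names(masks) %in% names(roles)))
    stop("every mask needs a role in 'roles'")
  roles <- roles[names(masks)]
  if (!all(roles %in% c("GTV", "CTV", "OAR")))
    stop("roles must be GTV, CTV or OAR")
  if (sum(roles == "GTV") != 1L || sum(roles == "CTV") != 1L)
    stop("structure set needs exactly one GTV and one CTV")
  for (m in masks) {
    stopifnot(inherits(m, "volume_grid"))
    if (!all(m$values %in% c(0, 1)))
      stop("masks must contain only 0/1")
  }
  do.call(check_congruent, c(masks, list(what = "structure-set masks")))
  gtv <- masks[[names(roles)[roles == "GTV"]]]
  ctv <- masks[[names(roles)[roles == "CTV"]]]
  if (any(gtv$values > ctv$values))
    stop("GTV must be a subset of CTV")
  structure(list(masks = masks, roles = roles), class = "structure_set")
}

#' Extract a mask, or the GTV/CTV, from a structure set
#'
#' @param structures a [structure_set].
#' @param name mask name.
#' @return a binary [volume_grid].
#' @export
roi_mask <- function(structures, name) {
  stopifnot(inherits(structures, "structure_set"))
  if (!name %in% names(structures$masks))
    stop("no ROI named '", name, "' in the structure set (have: ",
         paste(names(structures$masks), collapse = ", "), ")")
  structures$masks[[name]]
}

#' @rdname roi_mask
#' @export
gtv_mask <- function(structures) {
  roi_mask(structures, names(structures$roles)[structures$roles == "GTV"])
}

#' @rdname roi_mask
#' @export
ctv_mask <- function(structures) {
  roi_mask(structures, names(structures$roles)[structures$roles == "CTV"])
}

#' @rdname roi_mask
#' @export
oar_names <- function(structures) {
  names(structures$roles)[structures$roles == "OAR"]
}

#' @export
print.structure_set <- function(x, ...) {
  cat("<structure_set> with", length(x$masks), "ROI(s):\n")
  for (nm in names(x$masks)) {
    cat(sprintf("  %-14s %-4s %d voxels\n", nm, x$roles[[nm]],
                sum(x$masks[[nm]]$values)))
  }
  invisible(x)
}

# internal: safety-margin mask CTV \ GTV
margin_mask <- function(structures) {
  ctv <- ctv_mask(structures)
  gtv <- gtv_mask(structures)
  with_values(ctv, pmax(ctv$values - gtv$values, 0))
}
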