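#' Prescription parameters
#'
#' Bounds and fractionation for the cellularity-to-dose mapping. Defaults
#' are the skull-base chordoma protocol: a minimum (standard-of-care) GTV
#' dose of 74 Gy(RBE), an escalated cap of 81 Gy(RBE) (110% of standard of
#' care, as printed, not 74 x 1.10 = 81.4), delivered in 37 fractions.
#'
#' @param d_min minimum prescribed dose, Gy(RBE).
#' @param d_max maximum prescribed dose, Gy(RBE); must be >= `d_min`.
#' @param n_fractions number of fractions (>= 1).
#' @return an object of class `prescription_params`.
#' @export
prescription_params <- function(d_min = 74, d_max = 81, n_fractions = 37L) {
  if (!(d_min > 0) || !(d_max >= d_min))
    stop("need d_max >= d_min > 0 (Gy(RBE))")
  n_fractions <- as.integer(n_fractions)
  if (n_fractions < 1L) stop("'n_fractions' must be >= 1")
  structure(list(d_min = d_min, d_max = d_max, n_fractions = n_fractions),
            class = "prescription_params")
}

#' Convert a cell-density map to cells per voxel
#'
#' Multiplies a density field (cells/mm^3) by the voxel volume (mm^3) to
#' obtain the per-voxel clonogen count used by the prescription mapping and
#' the tumour control probability model.
#'
#' @param density a [volume_grid] of nonnegative cell densities, cells/mm^3.
#' @return a [volume_grid] of cells/voxel.
#' @export
cells_per_voxel <- function(density) {
  stopifnot(inherits(density, "volume_grid"))
  if (any(density$values < 0)) stop("cell densities must be nonnegative")
  with_values(density, density$values * voxel_volume(density))
}

#' Build the dose-painting prescription map
#'
#' Linear cellularity-to-dose mapping on the GTV with a safety-margin floor:
#' inside the GTV each voxel is prescribed
#' \deqn{D_i = (D_{max}-D_{min})\,\frac{\rho_i-\rho_{min}}{\rho_{max}-\rho_{min}} + D_{min},}
#' where \eqn{\rho_{min}},\eqn{\rho_{max}} are the cells-per-voxel extremes
#' observed in this patient's GTV; every voxel of the CTV-minus-GTV safety
#' margin is prescribed the floor \eqn{D_{min}}; voxels outside the CTV are
#' stored as 0 (undefined). The inverse map \eqn{D_{max} - D_i}, used as
#' background dose by a treatment planning system optimising toward a
#' uniform \eqn{D_{max}}, is computed alongside.
#'
#' If the GTV cellularity is flat (\eqn{\rho_{max} = \rho_{min}}) the linear
#' map is indeterminate and the whole GTV receives \eqn{D_{min}} (standard
#' of care), with a warning. Cellularity values outside the GTV extremes
#' (possible after interpolation) are clamped before mapping.
#'
#' @param rho a [volume_grid] of cells/voxel (finite, nonnegative on GTV).
#' @param structures a [structure_set] with GTV and CTV.
#' @param params [prescription_params].
#' @return an object of class `prescription_map` with elements `presc` and
#'   `inverse` ([volume_grid]s), `rho_min`, `rho_max`, and `params`.
#' @export
make_prescription <- function(rho, structures, params = prescription_params()) {
  stopifnot(inherits(rho, "volume_grid"),
            inherits(structures, "structure_set"),
            inherits(params, "prescription_params"))
  gtv <- gtv_mask(structures)
  ctv <- ctv_mask(structures)
  check_congruent(rho, gtv, what = "cellularity and masks")
  g <- gtv$values > 0
  if (!any(g)) stop("empty GTV")
  rg <- rho$values[g]
  if (any(!is.finite(rg)) || any(rg < 0))
    stop("cellularity must be finite and nonnegative on the GTV")
  rho_min <- min(rg)
  rho_max <- max(rg)

  presc <- array(0, dim(rho$values))
  presc[ctv$values > 0] <- params$d_min  # margin floor (and GTV baseline)
  if (rho_max > rho_min) {
    r <- pmin(pmax(rho$values[g], rho_min), rho_max)
    presc[g] <- (params$d_max - params$d_min) * (r - rho_min) /
      (rho_max - rho_min) + params$d_min
  } else {
    warning("flat GTV cellularity (rho_max == rho_min): ",
            "prescribing d_min uniformly")
  }
  out <- structure(list(
    presc = with_values(rho, presc),
    inverse = NULL, rho_min = rho_min, rho_max = rho_max, params = params
  ), class = "prescription_map")
  out$inverse <- make_inverse(out, params)
  out
}

#' Build a uniform (standard-of-care) prescription
#'
#' Flat `d_min` over the whole CTV — the comparator arm for dose painting.
#'
#' @inheritParams make_prescription
#' @return a `prescription_map` with constant prescription on the CTV.
#' @export
make_uniform_prescription <- function(structures,
                                      params = prescription_params()) {
  stopifnot(inherits(structures, "structure_set"))
  ctv <- ctv_mask(structures)
  presc <- ctv$values * params$d_min
  out <- structure(list(
    presc = with_values(ctv, presc), inverse = NULL,
    rho_min = NA_real_, rho_max = NA_real_, params = params
  ), class = "prescription_map")
  out$inverse <- make_inverse(out, params)
  out
}

#' Inverse prescription map
#'
#' `d_max` minus the prescription on every prescribed (nonzero) voxel, zero
#' elsewhere. Imported into a planning system as background dose so that
#' optimising the summed dose toward a uniform `d_max` delivers the
#' heterogeneous prescription.
#'
#' @param prescription a `prescription_map`.
#' @param params [prescription_params] (defaults to those stored in the map).
#' @return a [volume_grid] with values in `[0, d_max - d_min]`.
#' @export
make_inverse <- function(prescription, params = prescription$params) {
  stopifnot(inherits(prescription, "prescription_map"))
  p <- prescription$presc$values
  on_ctv <- p > 0
  if (any(p[on_ctv] < params$d_min - 1e-9) ||
      any(p[on_ctv] > params$d_max + 1e-9))
    stop("prescription out of [d_min, d_max] on the CTV")
  inv <- array(0, dim(p))
  inv[on_ctv] <- params$d_max - p[on_ctv]
  with_values(prescription$presc, inv)
}

#' @export
print.prescription_map <- function(x, ...) {
  p <- x$presc$values
  on <- p > 0
  cat("<prescription_map> ", sum(on), " prescribed voxels in [",
      format(min(p[on])), ", ", format(max(p[on])), "] Gy(RBE)\n", sep = "")
  if (is.finite(x$rho_min))
    cat("  GTV cellularity extremes: ", format(x$rho_min), " - ",
        format(x$rho_max), " cells/voxel\n", sep = "")
  invisible(x)
}
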