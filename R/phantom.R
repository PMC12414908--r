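#' Specify a synthetic dose-painting phantom
#'
#' Defines a fully synthetic "patient": an ellipsoidal gross tumour volume
#' (GTV) inside a clinical target volume (CTV = GTV dilated by a safety
#' margin), spherical organs at risk, a spatially correlated strictly
#' positive clonogen-density field on the GTV, and a perturbation model for
#' "delivered" plan doses (Gaussian blur + white noise + localized hotspots
#' in the CTV-minus-GTV margin). All randomness is governed by `seed`.
#'
#' Cellularity is a smoothed lognormal field: white Gaussian noise is
#' smoothed to the stated correlation length, standardised to unit marginal
#' variance, and exponentiated, so each voxel's clonogen density is
#' lognormal(`cell_log_mean`, `cell_log_sd`) in cells/mm^3 with spatial
#' correlation. The plan perturbation knobs let the phantom reproduce, one
#' knob each, the qualitative behaviours of optimised plans: slightly
#' imperfect conformity (blur/noise) and hotspots in the safety margin.
#'
#' @param shape integer(3) grid dimensions (voxels).
#' @param spacing numeric(3) voxel spacing in mm.
#' @param gtv_center world centre of the GTV in mm (`NULL` = grid centre).
#' @param gtv_semiaxes numeric(3) GTV ellipsoid semi-axes in mm.
#' @param ctv_margin isotropic GTV-to-CTV dilation margin in mm (> 0).
#' @param oars named list of `list(center=, radius=)` spheres (mm); centres
#'   relative to the GTV centre.
#' @param cell_log_mean,cell_log_sd log-mean and log-sd of clonogen density
#'   (cells/mm^3); `cell_log_sd = 0` gives a flat field.
#' @param cell_corr_length Gaussian correlation length of the field, mm.
#' @param blur_fwhm plan-dose blur FWHM in mm (0 = no blur).
#' @param noise_sd additive white-noise sd in Gy(RBE) (0 = none).
#' @param hotspot_amplitude,hotspot_n,hotspot_sigma margin-hotspot height in
#'   Gy(RBE), count, and Gaussian width (mm).
#' @param falloff_sigma Gaussian falloff length (mm) used to extend the
#'   prescription smoothly outside the CTV.
#' @param seed integer seed controlling all random draws.
#' @return an object of class `phantom_spec`.
#' @examples
#' spec <- phantom_spec(seed = 1)
#' st <- make_structures(spec)
#' rho <- make_cellularity(spec, st)
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L),
                         spacing = c(2, 2, 2),
                         gtv_center = NULL,
                         gtv_semiaxes = c(18, 14, 12),
                         ctv_margin = 6,
                         oars = list(
                           brainstem = list(center = c(34, 0, 0), radius = 8),
                           chiasm = list(center = c(-28, 14, 0), radius = 4),
                           cochlea = list(center = c(0, -32, 12), radius = 3)
                         ),
                         cell_log_mean = log(150),
                         cell_log_sd = 0.6,
                         cell_corr_length = 6,
                         blur_fwhm = 4,
                         noise_sd = 0.8,
                         hotspot_amplitude = 4,
                         hotspot_n = 2L,
                         hotspot_sigma = 3,
                         falloff_sigma = 5,
                         seed = 1L) {
  shape <- as.integer(shape)
  spacing <- as.numeric(spacing)
  stopifnot(length(shape) == 3L, all(shape >= 8L),
            length(spacing) == 3L, all(spacing > 0))
  extent <- (shape - 1) * spacing
  if (is.null(gtv_center)) gtv_center <- extent / 2
  if (ctv_margin <= 0) stop("'ctv_margin' must be > 0 so CTV \\ GTV is nonempty")
  if (cell_log_sd < 0) stop("'cell_log_sd' must be >= 0")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  # GTV (with CTV margin) must fit inside the grid
  if (any(gtv_center - gtv_semiaxes - ctv_margin < 0) ||
      any(gtv_center + gtv_semiaxes + ctv_margin > extent))
    stop("GTV plus CTV margin does not fit inside the grid")
  for (nm in names(oars)) {
    o <- oars[[nm]]
    ctr <- gtv_center + o$center
    if (any(ctr - o$radius < 0) || any(ctr + o$radius > extent))
      stop("OAR '", nm, "' does not fit inside the grid")
  }
  structure(list(
    shape = shape, spacing = spacing, gtv_center = as.numeric(gtv_center),
    gtv_semiaxes = as.numeric(gtv_semiaxes), ctv_margin = ctv_margin,
    oars = oars, cell_log_mean = cell_log_mean, cell_log_sd = cell_log_sd,
    cell_corr_length = cell_corr_length, blur_fwhm = blur_fwhm,
    noise_sd = noise_sd, hotspot_amplitude = hotspot_amplitude,
    hotspot_n = as.integer(hotspot_n), hotspot_sigma = hotspot_sigma,
    falloff_sigma = falloff_sigma, seed = as.integer(seed)
  ), class = "phantom_spec")
}

# internal: deterministic substream seeds, kept below 2^31
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 48271 + offset) %% 2147483647)
}

# internal: empty grid of the spec geometry
spec_grid <- function(spec, values = 0) {
  volume_grid(array(values, spec$shape), spacing = spec$spacing)
}

# internal: world coordinate arrays (identity orientation) of a spec grid
spec_coords <- function(spec) {
  list(
    x = (seq_len(spec$shape[1]) - 1) * spec$spacing[1],
    y = (seq_len(spec$shape[2]) - 1) * spec$spacing[2],
    z = (seq_len(spec$shape[3]) - 1) * spec$spacing[3]
  )
}

# internal: binary ellipsoid mask on the spec grid (centre/semiaxes in mm)
ellipsoid_array <- function(spec, center, semiaxes) {
  co <- spec_coords(spec)
  u2 <- ((co$x - center[1]) / semiaxes[1])^2
  v2 <- ((co$y - center[2]) / semiaxes[2])^2
  w2 <- ((co$z - center[3]) / semiaxes[3])^2
  d <- outer(outer(u2, v2, "+"), w2, "+")
  array(as.numeric(d <= 1), spec$shape)
}

# internal: exact grid dilation of a binary array by a ball of radius mm
dilate_ball <- function(mask, spacing, radius) {
  r <- floor(radius / spacing)
  offs <- expand.grid(dx = -r[1]:r[1], dy = -r[2]:r[2], dz = -r[3]:r[3])
  d2 <- (offs$dx * spacing[1])^2 + (offs$dy * spacing[2])^2 +
    (offs$dz * spacing[3])^2
  offs <- offs[d2 <= radius^2, , drop = FALSE]
  dm <- dim(mask)
  out <- array(FALSE, dm)
  m <- mask > 0
  for (k in seq_len(nrow(offs))) {
    sx <- offs$dx[k]; sy <- offs$dy[k]; sz <- offs$dz[k]
    xs <- max(1, 1 + sx):min(dm[1], dm[1] + sx)
    ys <- max(1, 1 + sy):min(dm[2], dm[2] + sy)
    zs <- max(1, 1 + sz):min(dm[3], dm[3] + sz)
    out[xs, ys, zs] <- out[xs, ys, zs] | m[xs - sx, ys - sy, zs - sz]
  }
  array(as.numeric(out), dm)
}

# internal: approximate distance (mm) outside a binary region, by successive
# shell dilations of one-voxel thickness; voxels beyond max_dist get max_dist
outside_distance <- function(mask, spacing, max_dist) {
  h <- min(spacing)
  steps <- ceiling(max_dist / h)
  dist <- array(max_dist, dim(mask))
  dist[mask > 0] <- 0
  cur <- mask
  for (s in seq_len(steps)) {
    nxt <- dilate_ball(cur, spacing, h * 1.0001)
    dist[nxt > cur] <- s * h
    cur <- nxt
  }
  dist
}

# internal: Gaussian kernel matrix along one axis; rows normalised to sum 1
# when normalize = TRUE (preserves constants; Neumann-like boundary)
axis_kernel <- function(n, spacing, sigma, normalize = TRUE) {
  if (sigma <= 0) return(diag(n))
  i <- seq_len(n)
  K <- exp(-outer(i, i, "-")^2 * spacing^2 / (2 * sigma^2))
  K[abs(outer(i, i, "-")) * spacing > 4 * sigma] <- 0
  if (normalize) K <- K / rowSums(K)
  K
}

# internal: apply a matrix along one axis of a 3-D array
apply_axis <- function(arr, K, axis) {
  dm <- dim(arr)
  perm <- switch(axis, `1` = c(1, 2, 3), `2` = c(2, 1, 3), `3` = c(3, 1, 2))
  a <- aperm(arr, perm)
  pdm <- dim(a)
  a <- K %*% matrix(a, pdm[1], pdm[2] * pdm[3])
  dim(a) <- pdm
  aperm(a, order(perm))
}

# internal: separable Gaussian smoothing (sigma in mm)
smooth_gaussian <- function(arr, spacing, sigma, normalize = TRUE) {
  if (sigma <= 0) return(arr)
  for (ax in 1:3) {
    arr <- apply_axis(arr, axis_kernel(dim(arr)[ax], spacing[ax], sigma,
                                       normalize), ax)
  }
  arr
}

#' Generate the phantom structure set
#'
#' Builds the ellipsoidal GTV, the CTV as the exact grid dilation of the GTV
#' by the spec margin (so GTV is a strict subset of CTV), and spherical OARs
#' disjoint from the GTV.
#'
#' @param spec a [phantom_spec].
#' @return a [structure_set].
#' @export
make_structures <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  gtv <- ellipsoid_array(spec, spec$gtv_center, spec$gtv_semiaxes)
  if (sum(gtv) == 0) stop("GTV is empty on this grid")
  ctv <- dilate_ball(gtv, spec$spacing, spec$ctv_margin)
  if (sum(ctv) <= sum(gtv))
    stop("CTV margin too small for this grid spacing: CTV \\ GTV is empty")
  masks <- list(GTV = with_values(spec_grid(spec), gtv),
                CTV = with_values(spec_grid(spec), ctv))
  roles <- c(GTV = "GTV", CTV = "CTV")
  for (nm in names(spec$oars)) {
    o <- spec$oars[[nm]]
    sph <- ellipsoid_array(spec, spec$gtv_center + o$center,
                           rep(o$radius, 3))
    if (any(sph * gtv > 0)) stop("OAR '", nm, "' overlaps the GTV")
    masks[[nm]] <- with_values(spec_grid(spec), sph)
    roles[nm] <- "OAR"
  }
  structure_set(masks, roles)
}

#' Generate the phantom cellularity map (cells per voxel)
#'
#' Draws the correlated lognormal clonogen-density field (cells/mm^3) on the
#' GTV and multiplies by the voxel volume to obtain cells per voxel. Strictly
#' positive inside the GTV, zero outside; bit-reproducible under the spec
#' seed.
#'
#' @param spec a [phantom_spec].
#' @param structures the [structure_set] from [make_structures].
#' @return a [volume_grid] of cells/voxel.
#' @export
make_cellularity <- function(spec, structures) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(structures, "structure_set"))
  gtv <- gtv_mask(structures)$values
  if (sum(gtv) == 0) stop("empty GTV")
  if (spec$cell_log_sd == 0) {
    dens <- exp(spec$cell_log_mean) * gtv
  } else {
    set.seed(derive_seed(spec$seed, 1L))
    z <- array(stats::rnorm(prod(spec$shape)), spec$shape)
    if (spec$cell_corr_length > 0) {
      Ks <- lapply(1:3, function(ax)
        axis_kernel(spec$shape[ax], spec$spacing[ax], spec$cell_corr_length,
                    normalize = FALSE))
      for (ax in 1:3) z <- apply_axis(z, Ks[[ax]], ax)
      # standardise to exact unit marginal variance: the smoothed value at
      # voxel (i,j,k) has variance prod_ax sum_j K_ax[i,j]^2
      s <- lapply(Ks, function(K) sqrt(rowSums(K^2)))
      sd_arr <- outer(outer(s[[1]], s[[2]]), s[[3]])
      z <- z / sd_arr
    }
    dens <- exp(spec$cell_log_mean + spec$cell_log_sd * z) * gtv
  }
  cells_per_voxel(with_values(spec_grid(spec), dens))
}

#' Generate a synthetic "delivered" plan dose
#'
#' Emulates an optimised plan for a given prescription: the prescription is
#' extended smoothly outside the CTV by Gaussian falloff, blurred with the
#' spec blur kernel, perturbed with white noise, and topped with localized
#' Gaussian hotspots centred at random voxels of the safety margin
#' (CTV minus GTV). The result is clipped at zero. With all perturbation
#' parameters zero the dose equals the prescription exactly on the CTV.
#'
#' The random stream depends only on the spec seed, not on the prescription,
#' so paired plan arms (dose painting vs uniform) built from the same spec
#' share identical noise and hotspot locations.
#'
#' @param spec a [phantom_spec].
#' @param prescription a [prescription_map] defined on the CTV.
#' @param structures the [structure_set] from [make_structures].
#' @return a [volume_grid] of dose in Gy(RBE).
#' @export
make_plan_dose <- function(spec, prescription, structures) {
  stopifnot(inherits(spec, "phantom_spec"),
            inherits(prescription, "prescription_map"),
            inherits(structures, "structure_set"))
  ctv <- ctv_mask(structures)$values
  presc <- prescription$presc$values
  if (any(presc[ctv > 0] <= 0))
    stop("prescription must be positive on every CTV voxel")

  # extend the prescription outside the CTV with a penumbra: nearest
  # prescription level (masked normalized convolution) decayed by a Gaussian
  # of the distance to the CTV surface
  sm_p <- smooth_gaussian(presc * ctv, spec$spacing, spec$falloff_sigma,
                          normalize = TRUE)
  sm_m <- smooth_gaussian(ctv, spec$spacing, spec$falloff_sigma,
                          normalize = TRUE)
  level <- sm_p / pmax(sm_m, 1e-9)
  dist <- outside_distance(ctv, spec$spacing, 4 * spec$falloff_sigma)
  ext <- level * exp(-dist^2 / (2 * spec$falloff_sigma^2))
  dose <- ctv * presc + (1 - ctv) * ext
  if (spec$blur_fwhm > 0) {
    dose <- smooth_gaussian(dose, spec$spacing,
                            spec$blur_fwhm / (2 * sqrt(2 * log(2))),
                            normalize = TRUE)
  }

  set.seed(derive_seed(spec$seed, 2L))
  if (spec$noise_sd > 0)
    dose <- dose + array(stats::rnorm(prod(spec$shape), 0, spec$noise_sd),
                         spec$shape)
  if (spec$hotspot_n > 0) {
    margin_idx <- which(ctv > 0 & gtv_mask(structures)$values == 0)
    if (spec$hotspot_n > length(margin_idx))
      stop("hotspot count exceeds the number of CTV \\ GTV margin voxels")
    centres <- sample(margin_idx, spec$hotspot_n)
    co <- spec_coords(spec)
    for (ci in centres) {
      ijk <- arrayInd(ci, spec$shape)
      d2 <- outer(outer((co$x - co$x[ijk[1]])^2,
                        (co$y - co$y[ijk[2]])^2, "+"),
                  (co$z - co$z[ijk[3]])^2, "+")
      dose <- dose +
        spec$hotspot_amplitude * exp(-d2 / (2 * spec$hotspot_sigma^2))
    }
  }
  with_values(spec_grid(spec), pmax(dose, 0))
}

#' Simulate one complete synthetic patient
#'
#' Convenience wrapper: structures, cellularity, dose-painting and uniform
#' prescriptions, and one synthetic plan dose per prescription.
#'
#' @param spec a [phantom_spec].
#' @param params [prescription_params] for the dose-painting prescription.
#' @return a list with elements `spec`, `structures`, `cellularity`,
#'   `presc_dp`, `presc_uniform`, `dose_dp`, `dose_uniform`.
#' @export
simulate_phantom <- function(spec, params = prescription_params()) {
  structures <- make_structures(spec)
  rho <- make_cellularity(spec, structures)
  presc_dp <- make_prescription(rho, structures, params)
  presc_un <- make_uniform_prescription(structures, params)
  list(
    spec = spec, structures = structures, cellularity = rho,
    presc_dp = presc_dp, presc_uniform = presc_un,
    dose_dp = make_plan_dose(spec, presc_dp, structures),
    dose_uniform = make_plan_dose(spec, presc_un, structures)
  )
}
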