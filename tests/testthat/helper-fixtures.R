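# Shared fixtures: small phantoms and toy grids, built in code at test time.

# desk-scale phantom: ~350 GTV voxels, generates in well under a second
small_spec <- function(seed = 1, ...) {
  phantom_spec(
    shape = c(32L, 32L, 32L), spacing = c(2, 2, 2),
    gtv_semiaxes = c(10, 8, 8), ctv_margin = 4,
    oars = list(brainstem = list(center = c(20, 0, 0), radius = 5)),
    seed = seed, ...
  )
}

# same geometry, no plan perturbation at all
quiet_spec <- function(seed = 1, ...) {
  small_spec(seed = seed, blur_fwhm = 0, noise_sd = 0, hotspot_n = 0L, ...)
}

# a grid from a vector/array with default unit geometry
toy_grid <- function(values, dm = NULL, spacing = c(1, 1, 1)) {
  if (is.null(dm)) dm <- dim(values)
  volume_grid(array(values, dm), spacing = spacing)
}

# single-ROI mask covering given linear indices of a grid
toy_mask <- function(grid, idx = seq_along(grid$values)) {
  m <- array(0, dim(grid$values))
  m[idx] <- 1
  with_values(grid, m)
}

# independent brute-force oracle for nearest-neighbour affine resampling:
# loops over output voxels, maps centres through the inverse transform
oracle_resample_nearest <- function(grid, transform, reference, fill = 0) {
  dm <- dim(reference$values)
  out <- array(fill, dm)
  inv <- solve(transform$matrix)
  sdm <- dim(grid$values)
  for (i in seq_len(dm[1])) for (j in seq_len(dm[2])) for (k in seq_len(dm[3])) {
    w <- reference$direction %*% ((c(i, j, k) - 1) * reference$spacing) +
      reference$origin
    s <- inv %*% c(w, 1)
    cont <- t(grid$direction) %*% (s[1:3] - grid$origin) / grid$spacing
    n <- round(cont)
    if (all(n >= 0) && all(n <= sdm - 1))
      out[i, j, k] <- grid$values[n[1] + 1, n[2] + 1, n[3] + 1]
  }
  out
}

# independent exact Wilcoxon two-sided p: full 2^m sign-flip enumeration
# over bit patterns (distinct coding path from the implementation)
oracle_wilcoxon_exact <- function(x, y) {
  d <- (x - y)[x != y]
  m <- length(d)
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ws <- vapply(0:(2^m - 1), function(b) {
    bits <- as.integer(intToBits(b))[1:m]
    sum(r[bits == 1])
  }, numeric(1))
  min(1, 2 * min(mean(ws <= v + 1e-9), mean(ws >= v - 1e-9)))
}
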