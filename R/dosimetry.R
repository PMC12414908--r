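#' Plan conformity quality factor
#'
#' Scores how closely a planned dose matches a per-voxel prescription over a
#' region of interest:
#' \deqn{QF = 100 - \frac{100}{n}\sum_{i\in ROI}
#'   \frac{|D^{plan}_i - D^{presc}_i|}{D^{presc}_i},}
#' the mean absolute per-voxel relative deviation subtracted from 100%.
#' QF = 100 corresponds to an ideal plan; a uniform 1% relative deviation
#' gives exactly 99. The per-voxel map stores
#' \eqn{100 - 100\,|D^{plan}_i - D^{presc}_i| / D^{presc}_i} on the ROI and
#' 0 elsewhere (with the ROI itself as validity mask).
#'
#' @param plan a [volume_grid] of planned dose, Gy(RBE).
#' @param presc a [volume_grid] of prescribed dose, strictly positive on the
#'   ROI.
#' @param roi a binary [volume_grid] mask (nonempty).
#' @return an object of class `qf_result`: `qf` (percent), `per_voxel_map`
#'   (a [volume_grid]), `n_voxels`.
#' @export
quality_factor <- function(plan, presc, roi) {
  stopifnot(inherits(plan, "volume_grid"), inherits(presc, "volume_grid"),
            inherits(roi, "volume_grid"))
  check_congruent(plan, presc, roi, what = "plan, prescription and ROI")
  sel <- roi$values > 0
  n <- sum(sel)
  if (n == 0) stop("empty ROI")
  p <- presc$values[sel]
  if (any(p <= 0))
    stop("prescription must be strictly positive on every ROI voxel")
  dev <- 100 * abs(plan$values[sel] - p) / p
  map <- array(0, dim(plan$values))
  map[sel] <- 100 - dev
  structure(list(
    qf = 100 - mean(dev),
    per_voxel_map = with_values(plan, map),
    n_voxels = n
  ), class = "qf_result")
}

#' @export
print.qf_result <- function(x, ...) {
  cat(sprintf("<qf_result> QF = %.3f%% over %d voxels\n", x$qf, x$n_voxels))
  invisible(x)
}

#' Dose received by the hottest x% of an ROI (DVH quantile)
#'
#' Nearest-rank definition: the smallest dose `d` such that at least
#' `volume_pct`% of the ROI volume receives a dose of at least `d`; computed
#' from the empirical distribution without interpolation. `dose_at_volume(.,
#' 95)` is D95% (coverage), `dose_at_volume(., 1)` is D1% (near-maximum).
#'
#' @param dose a [volume_grid], Gy(RBE).
#' @param roi a binary [volume_grid] mask (nonempty).
#' @param volume_pct percentage of ROI volume in (0, 100].
#' @return dose in Gy(RBE).
#' @export
dose_at_volume <- function(dose, roi, volume_pct) {
  stopifnot(inherits(dose, "volume_grid"), inherits(roi, "volume_grid"))
  check_congruent(dose, roi, what = "dose and ROI")
  if (!(volume_pct > 0 && volume_pct <= 100))
    stop("'volume_pct' must be in (0, 100]")
  d <- dose$values[roi$values > 0]
  if (length(d) == 0) stop("empty ROI")
  sorted <- sort(d, decreasing = TRUE)
  sorted[ceiling(volume_pct / 100 * length(d))]
}

#' ROI dose metrics
#'
#' Mean, median, maximum, minimum, D95% and D1% of the dose over an ROI
#' (sample statistics and nearest-rank DVH quantiles).
#'
#' @inheritParams dose_at_volume
#' @return an object of class `dose_metrics` with fields `d_mean`,
#'   `d_median`, `d_max`, `d_min`, `d_95`, `d_1` (all Gy(RBE)) and
#'   `n_voxels`.
#' @export
dose_metrics <- function(dose, roi) {
  stopifnot(inherits(dose, "volume_grid"), inherits(roi, "volume_grid"))
  check_congruent(dose, roi, what = "dose and ROI")
  d <- dose$values[roi$values > 0]
  if (length(d) == 0) stop("empty ROI")
  structure(list(
    d_mean = mean(d), d_median = stats::median(d),
    d_max = max(d), d_min = min(d),
    d_95 = dose_at_volume(dose, roi, 95),
    d_1 = dose_at_volume(dose, roi, 1),
    n_voxels = length(d)
  ), class = "dose_metrics")
}

#' @export
print.dose_metrics <- function(x, ...) {
  cat(sprintf(paste0("<dose_metrics> n=%d  mean=%.2f median=%.2f ",
                     "min=%.2f D95%%=%.2f D1%%=%.2f max=%.2f Gy(RBE)\n"),
              x$n_voxels, x$d_mean, x$d_median, x$d_min, x$d_95, x$d_1,
              x$d_max))
  invisible(x)
}

#' Generalized equivalent uniform dose
#'
#' The power mean of the voxel doses over an ROI,
#' \deqn{EUD_a = \Big(\frac{1}{n}\sum_i D_i^a\Big)^{1/a},}
#' with organ-specific parameter `a` (`a = 1` gives the mean dose; large
#' positive `a` approaches the maximum, weighting serial organs toward their
#' hottest voxels).
#'
#' @inheritParams dose_at_volume
#' @param a nonzero power-mean parameter (dimensionless).
#' @return EUD in Gy(RBE).
#' @export
eud <- function(dose, roi, a) {
  stopifnot(inherits(dose, "volume_grid"), inherits(roi, "volume_grid"))
  check_congruent(dose, roi, what = "dose and ROI")
  if (a == 0) stop("'a' must be nonzero")
  d <- dose$values[roi$values > 0]
  if (length(d) == 0) stop("empty ROI")
  if (any(d < 0)) stop("doses must be nonnegative")
  if (max(d) == 0) return(0)
  if (any(d == 0) && a < 0) return(0)  # power-mean limit with a zero dose
  # log-space power mean: stable for large |a| where d^a overflows
  ld <- a * log(d)
  m <- max(ld)
  exp((m + log(mean(exp(ld - m)))) / a)
}

#' Cumulative dose-volume histogram
#'
#' Percent of ROI volume receiving at least each dose level, tabulated at a
#' fixed bin width from 0 to the ROI maximum.
#'
#' @inheritParams dose_at_volume
#' @param bin_width dose bin width in Gy(RBE).
#' @return data.frame with columns `dose` (Gy(RBE)) and `volume_pct`.
#' @export
dvh <- function(dose, roi, bin_width = 0.1) {
  stopifnot(bin_width > 0)
  d <- dose$values[roi$values > 0]
  if (length(d) == 0) stop("empty ROI")
  breaks <- seq(0, max(d) + bin_width, by = bin_width)
  vol <- vapply(breaks, function(b) 100 * mean(d >= b), numeric(1))
  data.frame(dose = breaks, volume_pct = vol)
}

#' Define a clinical goal
#'
#' A machine-checkable dose objective or constraint for one ROI, in the
#' style of a planning-protocol goal sheet: a maximum-dose limit, a DVH
#' dose-at-volume limit (e.g. "max DVH 50 Gy(RBE) to 1% volume", or a target
#' coverage objective "min DVH 74 Gy(RBE) to 95% volume"), or an EUD limit.
#' Thresholds are inclusive: achieving exactly the threshold passes.
#'
#' @param roi ROI name (must exist in the structure set at evaluation).
#' @param metric `"max_dose"`, `"dvh"` (dose at volume), or `"eud"`.
#' @param limit `"max"` (achieved must be <= threshold) or `"min"`
#'   (achieved must be >= threshold, used for target coverage objectives).
#' @param threshold dose threshold, Gy(RBE), > 0.
#' @param volume_pct ROI volume percentage in (0, 100] (DVH goals only).
#' @param a EUD parameter (EUD goals only).
#' @param robust whether the protocol evaluates this goal robustly
#'   (carried as metadata; robust scenario evaluation is out of scope).
#' @return an object of class `clinical_goal`.
#' @export
clinical_goal <- function(roi, metric = c("max_dose", "dvh", "eud"),
                          limit = c("max", "min"), threshold,
                          volume_pct = NULL, a = NULL, robust = FALSE) {
  metric <- match.arg(metric)
  limit <- match.arg(limit)
  if (!(threshold > 0)) stop("'threshold' must be > 0")
  if (metric == "dvh") {
    if (is.null(volume_pct) || !(volume_pct > 0 && volume_pct <= 100))
      stop("DVH goals need 'volume_pct' in (0, 100]")
  }
  if (metric == "eud" && (is.null(a) || a == 0))
    stop("EUD goals need a nonzero 'a'")
  structure(list(roi = roi, metric = metric, limit = limit,
                 threshold = threshold, volume_pct = volume_pct, a = a,
                 robust = robust),
            class = "clinical_goal")
}

#' Default clinical-goal set for the chordoma protocol
#'
#' The target objectives and organ-at-risk constraints of the planning
#' protocol: CTV/GTV coverage (min DVH 74 Gy(RBE) to 95% volume), a CTV
#' maximum-dose constraint (83 Gy(RBE) for dose-painting plans, 76 for
#' uniform plans), and OAR limits for brainstem (max dose 61, robust),
#' chiasm (max DVH 54 to 1%), optic nerves (max DVH 50 to 1%), cochleae
#' (max EUD 45, a = 1), carotids (max DVH 75.5 to 1%), and temporal lobes
#' (max DVH 71 to 1.7%). Only goals whose ROI exists in a structure set are
#' evaluated.
#'
#' @param plan_type `"dose_painting"` or `"uniform"` (sets the CTV
#'   maximum-dose constraint).
#' @return list of [clinical_goal]s.
#' @export
default_clinical_goals <- function(plan_type = c("dose_painting", "uniform")) {
  plan_type <- match.arg(plan_type)
  ctv_max <- if (plan_type == "dose_painting") 83 else 76
  list(
    clinical_goal("GTV", "dvh", "min", 74, volume_pct = 95),
    clinical_goal("CTV", "dvh", "min", 74, volume_pct = 95),
    clinical_goal("CTV", "max_dose", "max", ctv_max),
    clinical_goal("brainstem", "max_dose", "max", 61, robust = TRUE),
    clinical_goal("chiasm", "dvh", "max", 54, volume_pct = 1),
    clinical_goal("optic_nerves", "dvh", "max", 50, volume_pct = 1),
    clinical_goal("cochlea", "eud", "max", 45, a = 1),
    clinical_goal("carotids", "dvh", "max", 75.5, volume_pct = 1),
    clinical_goal("temporal_lobes", "dvh", "max", 71, volume_pct = 1.7)
  )
}

#' Evaluate clinical goals against a dose distribution
#'
#' Computes each goal's achieved metric on its ROI and reports pass/fail
#' with inclusive thresholds (`max` goals pass when achieved <= threshold,
#' `min` goals when achieved >= threshold).
#'
#' @param dose a [volume_grid], Gy(RBE).
#' @param structures a [structure_set].
#' @param goals list of [clinical_goal]s.
#' @param skip_missing drop goals whose ROI is absent (`FALSE` = error).
#' @return data.frame with one row per goal: `roi`, `metric`, `limit`,
#'   `threshold`, `volume_pct`, `a`, `robust`, `achieved`, `pass`.
#' @export
evaluate_goals <- function(dose, structures, goals, skip_missing = FALSE) {
  stopifnot(inherits(dose, "volume_grid"), inherits(structures, "structure_set"))
  rows <- lapply(goals, function(g) {
    stopifnot(inherits(g, "clinical_goal"))
    if (!g$roi %in% names(structures$masks)) {
      if (skip_missing) return(NULL)
      stop("goal references missing ROI: ", g$roi)
    }
    roi <- roi_mask(structures, g$roi)
    achieved <- switch(g$metric,
      max_dose = max(dose$values[roi$values > 0]),
      dvh = dose_at_volume(dose, roi, g$volume_pct),
      eud = eud(dose, roi, g$a)
    )
    pass <- if (g$limit == "max") achieved <= g$threshold
            else achieved >= g$threshold
    data.frame(roi = g$roi, metric = g$metric, limit = g$limit,
               threshold = g$threshold,
               volume_pct = if (is.null(g$volume_pct)) NA_real_ else g$volume_pct,
               a = if (is.null(g$a)) NA_real_ else g$a,
               robust = g$robust, achieved = achieved, pass = pass,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, Filter(Negate(is.null), rows))
}
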