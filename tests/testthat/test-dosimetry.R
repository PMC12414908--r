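test_that("quality factor: identity gives 100, uniform 1% deviation gives 99", {
  presc <- toy_grid(rep(77, 27), c(3, 3, 3))
  roi <- toy_mask(presc)
  expect_equal(quality_factor(presc, presc, roi)$qf, 100)
  plan <- with_values(presc, presc$values * 1.01)
  expect_equal(quality_factor(plan, presc, roi)$qf, 99, tolerance = 1e-12)
  # strictly decreasing in |1 - k| for plan = k * presc
  qfs <- vapply(c(1, 1.02, 0.95, 1.1), function(k)
    quality_factor(with_values(presc, k * presc$values), presc, roi)$qf,
    numeric(1))
  expect_equal(qfs, 100 - 100 * abs(1 - c(1, 1.02, 0.95, 1.1)),
               tolerance = 1e-12)
})

test_that("quality factor matches the hand-summed toy oracle", {
  presc <- toy_grid(c(74, 77.5, 81, rep(1, 5)), c(2, 2, 2))
  plan <- toy_grid(c(74, 76, 82, rep(1, 5)), c(2, 2, 2))
  roi <- toy_mask(presc, 1:3)
  res <- quality_factor(plan, presc, roi)
  expect_equal(res$qf, 98.9433160759326, tolerance = 1e-12)
  expect_equal(res$n_voxels, 3L)
  # qf is the ROI mean of the per-voxel map
  expect_equal(mean(res$per_voxel_map$values[1:3]), res$qf,
               tolerance = 1e-9)
  expect_true(all(res$per_voxel_map$values[4:8] == 0))
})

test_that("quality factor is invariant to a common dose rescaling", {
  set.seed(15)
  presc <- toy_grid(runif(27, 70, 80), c(3, 3, 3))
  plan <- with_values(presc, presc$values + rnorm(27))
  roi <- toy_mask(presc)
  a <- quality_factor(plan, presc, roi)$qf
  b <- quality_factor(with_values(plan, 2.5 * plan$values),
                      with_values(presc, 2.5 * presc$values), roi)$qf
  expect_equal(a, b, tolerance = 1e-12)
})

test_that("quality factor rejects invalid prescriptions and geometry", {
  presc <- toy_grid(c(0, rep(70, 7)), c(2, 2, 2))
  roi <- toy_mask(presc)
  expect_error(quality_factor(presc, presc, roi), "strictly positive")
  other <- toy_grid(rep(70, 8), c(2, 2, 2), spacing = c(2, 2, 2))
  expect_error(quality_factor(other, presc, roi), "geometry")
  expect_error(quality_factor(presc, presc, toy_mask(presc, integer(0))),
               "empty ROI")
})

test_that("dose metrics: constant field collapses all metrics to that dose", {
  dose <- toy_grid(rep(63.5, 27), c(3, 3, 3))
  m <- dose_metrics(dose, toy_mask(dose))
  for (f in c("d_mean", "d_median", "d_max", "d_min", "d_95", "d_1"))
    expect_equal(m[[f]], 63.5)
})

test_that("DVH quantiles match the exhaustive sort-and-count oracle on 1..100", {
  dose <- toy_grid(sample(1:100), c(5, 5, 4))
  roi <- toy_mask(dose)
  # oracle: largest d with >= x% of voxels at >= d, by direct counting
  oracle_dxx <- function(x) {
    cand <- sort(unique(as.numeric(dose$values)), decreasing = TRUE)
    cand[which(vapply(cand, function(d) mean(dose$values >= d) >= x / 100,
                      logical(1)))[1]]
  }
  expect_equal(dose_at_volume(dose, roi, 95), oracle_dxx(95))
  expect_equal(dose_at_volume(dose, roi, 1), oracle_dxx(1))
  expect_equal(dose_at_volume(dose, roi, 95), 6)
  expect_equal(dose_at_volume(dose, roi, 1), 100)
  m <- dose_metrics(dose, roi)
  expect_equal(m$d_min, 1); expect_equal(m$d_max, 100)
})

test_that("dose-metric orderings hold on random fields and under permutation", {
  set.seed(16)
  for (trial in 1:20) {
    dose <- toy_grid(rlnorm(4^3, 4, 0.3), c(4, 4, 4))
    roi <- toy_mask(dose, sample(64, 40))
    m <- dose_metrics(dose, roi)
    expect_lte(m$d_min, m$d_95)
    expect_lte(m$d_95, m$d_median)
    expect_lte(m$d_median, m$d_1)
    expect_lte(m$d_1, m$d_max)
    expect_lte(m$d_min, m$d_mean)
    expect_lte(m$d_mean, m$d_max)
  }
  # order invariance: permuting the ROI voxel values leaves metrics unchanged
  dose <- toy_grid(rlnorm(27, 4, 0.5), c(3, 3, 3))
  roi <- toy_mask(dose)
  perm <- with_values(dose, array(sample(dose$values), c(3, 3, 3)))
  expect_equal(unclass(dose_metrics(dose, roi))[1:6],
               unclass(dose_metrics(perm, roi))[1:6])
})

test_that("EUD is the power mean: a = 1 gives the mean, uniform is a fixed point", {
  set.seed(17)
  dose <- toy_grid(rlnorm(27, 4, 0.4), c(3, 3, 3))
  roi <- toy_mask(dose)
  expect_equal(eud(dose, roi, 1), mean(dose$values), tolerance = 1e-12)
  unif <- toy_grid(rep(48, 27), c(3, 3, 3))
  for (a in c(-2, 1, 4, 20)) expect_equal(eud(unif, roi, a), 48)
  # direct-evaluation oracle on {10, 20, 40} with a = 4, and a-monotonicity
  d3 <- toy_grid(c(10, 20, 40, rep(1, 5)), c(2, 2, 2))
  r3 <- toy_mask(d3, 1:3)
  expect_equal(eud(d3, r3, 4), 30.8859061938766, tolerance = 1e-12)
  expect_gte(eud(d3, r3, 4), eud(d3, r3, 1))
  expect_error(eud(dose, roi, 0), "nonzero")
})

test_that("EUD approaches the maximum dose for large a", {
  set.seed(18)
  dose <- toy_grid(runif(64, 10, 70), c(4, 4, 4))
  roi <- toy_mask(dose)
  expect_equal(eud(dose, roi, 200), max(dose$values), tolerance = 0.02)
})

test_that("clinical goals evaluate with inclusive thresholds", {
  st <- make_structures(small_spec())
  dose <- with_values(ctv_mask(st), array(50, dim(ctv_mask(st)$values)))
  goals <- list(
    clinical_goal("brainstem", "max_dose", "max", 61),
    clinical_goal("brainstem", "eud", "max", 50, a = 1),  # exact boundary
    clinical_goal("CTV", "dvh", "min", 74, volume_pct = 95)
  )
  rep <- evaluate_goals(dose, st, goals)
  expect_equal(rep$achieved[1], 50)
  expect_true(rep$pass[1])
  expect_true(rep$pass[2])      # achieved == threshold passes
  expect_false(rep$pass[3])     # 50 Gy cannot cover a 74 Gy objective
  expect_error(evaluate_goals(dose, st,
                              list(clinical_goal("spine", "max_dose", "max", 45))),
               "missing ROI")
})

test_that("a constructed OAR hotspot fails exactly that goal", {
  st <- make_structures(small_spec())
  base <- with_values(ctv_mask(st), array(30, dim(ctv_mask(st)$values)))
  goals <- list(clinical_goal("brainstem", "max_dose", "max", 61),
                clinical_goal("brainstem", "eud", "max", 45, a = 1))
  before <- evaluate_goals(base, st, goals)
  expect_true(all(before$pass))
  hot <- base
  oar_idx <- which(roi_mask(st, "brainstem")$values > 0)
  hot$values[oar_idx[1]] <- 65   # single voxel above the 61 Gy(RBE) limit
  after <- evaluate_goals(hot, st, goals)
  expect_false(after$pass[1])
  expect_true(after$pass[2])     # one voxel barely moves the mean EUD
})

test_that("cumulative DVH starts at 100% volume and is non-increasing", {
  set.seed(19)
  dose <- toy_grid(runif(64, 0, 80), c(4, 4, 4))
  tab <- dvh(dose, toy_mask(dose), bin_width = 0.5)
  expect_equal(tab$volume_pct[1], 100)
  expect_true(all(diff(tab$volume_pct) <= 0))
  expect_equal(tab$volume_pct[nrow(tab)], 0)
})
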