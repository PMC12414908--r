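test_that("wilcoxon: identical arms give p = 1 with no test", {
  x <- c(1, 2, 3, 4, 5, 6)
  res <- wilcoxon_paired(x, x)
  expect_equal(res$p_value, 1)
  expect_equal(res$n_nonzero, 0L)
})

test_that("wilcoxon: six uniformly positive differences give exact p = 2/64", {
  x <- c(2, 3, 4, 5, 6, 7)
  y <- c(1, 2, 3, 4, 5, 6)
  res <- wilcoxon_paired(x, y)
  expect_equal(res$p_value, 2 / 2^6)
  expect_equal(res$statistic, 21)   # full positive rank sum 6*7/2
})

test_that("exact wilcoxon p matches the sign-flip enumeration oracle", {
  set.seed(22)
  for (trial in 1:30) {
    n <- sample(5:10, 1)
    x <- rnorm(n)
    y <- x + rnorm(n, mean = runif(1, -0.8, 0.8))
    res <- wilcoxon_paired(x, y)
    expect_equal(res$p_value, oracle_wilcoxon_exact(x, y), tolerance = 1e-12)
  }
})

test_that("exact wilcoxon agrees with stats::wilcox.test on tie-free data", {
  set.seed(23)
  for (trial in 1:10) {
    x <- rnorm(12)
    y <- x + rnorm(12, 0.3)
    ours <- wilcoxon_paired(x, y)
    ref <- stats::wilcox.test(x, y, paired = TRUE, exact = TRUE)
    expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-12)
    expect_equal(ours$statistic, unname(ref$statistic))
  }
})

test_that("large samples fall back to a sane normal approximation", {
  set.seed(24)
  x <- rnorm(40)
  y <- x + rnorm(40, 0.5)
  ours <- wilcoxon_paired(x, y)
  ref <- stats::wilcox.test(x, y, paired = TRUE, exact = FALSE,
                            correct = TRUE)
  expect_equal(ours$method, "normal approximation")
  expect_equal(ours$p_value, unname(ref$p.value), tolerance = 1e-6)
})

test_that("holm-sidak adjustment follows the step-down formula", {
  expect_equal(holm_sidak(0.037), 0.037)              # m = 1: unchanged
  # hand-stepped oracle for (0.01, 0.04, 0.03):
  # sorted (0.01, 0.03, 0.04) -> 1-(1-p)^(3,2,1) = (0.029701, 0.0591, 0.04)
  # -> cummax (0.029701, 0.0591, 0.0591) -> back to input order
  expect_equal(holm_sidak(c(0.01, 0.04, 0.03)),
               c(0.029701, 0.0591, 0.0591), tolerance = 1e-12)
  expect_equal(holm_sidak(rep(0.2, 4)), rep(1 - 0.8^4, 4))  # symmetry
  set.seed(25)
  p <- runif(8)
  adj <- holm_sidak(p)
  expect_true(all(adj >= p))                          # never below raw
  expect_true(all(adj <= 1))
  expect_true(all(diff(adj[order(p)]) >= 0))          # monotone when sorted
  expect_error(holm_sidak(c(0.5, 1.2)), "0, 1")
})

test_that("zero-perturbation cohort: QF = 100 both arms, painting never loses TCP", {
  specs <- lapply(1:3, function(s) quiet_spec(seed = s))
  cohort <- run_cohort(specs)
  m <- cohort$metrics
  expect_equal(nrow(m), 6)                     # 3 patients x 2 arms
  expect_equal(m$QF_GTV, rep(100, 6))
  expect_equal(m$QF_CTV, rep(100, 6))
  dp <- m[m$arm == "dose_painting", ]
  un <- m[m$arm == "uniform", ]
  expect_equal(dp$patient, un$patient)         # paired design
  expect_true(all(dp$TCP > un$TCP))            # strict: cellularity non-flat
})

test_that("cohort runs are deterministic and traceable to seeds", {
  specs <- lapply(4:5, function(s) quiet_spec(seed = s))
  a <- run_cohort(specs)
  b <- run_cohort(specs)
  expect_identical(a$metrics, b$metrics)
  expect_equal(sort(unique(a$metrics$seed)), 4:5)
})

test_that("dose painting escalates the GTV maximum dose across a cohort", {
  specs <- lapply(6:10, function(s) small_spec(seed = s))
  cohort <- run_cohort(specs)
  m <- cohort$metrics
  dp <- m[m$arm == "dose_painting", ]
  un <- m[m$arm == "uniform", ]
  expect_gt(median(dp$d_max_GTV), median(un$d_max_GTV))
  tests <- compare_arms(cohort, metrics = c("TCP", "d_max_GTV"))
  expect_true(all(tests$p_adjusted >= tests$p_raw))
  expect_equal(tests$significant, tests$p_adjusted < 0.05)
})

test_that("reports are written completely and reproducibly", {
  specs <- lapply(1:2, function(s) quiet_spec(seed = s))
  cohort <- run_cohort(specs)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  paths <- make_report(cohort, tests = NULL, dir = dir1)
  expect_true(file.exists(file.path(dir1, "metrics.csv")))
  expect_true(any(grepl("boxplot_QF_GTV", paths)))
  make_report(cohort, tests = NULL, dir = dir2)
  expect_identical(readLines(file.path(dir1, "metrics.csv")),
                   readLines(file.path(dir2, "metrics.csv")))
  got <- utils::read.csv(file.path(dir1, "metrics.csv"))
  # 2 arms x 2 patients, QF + TCP + 6 metrics x 2 target ROIs per record
  expect_equal(nrow(got), 4)
  expect_true(all(c("QF_GTV", "QF_CTV", "TCP",
                    paste0(rep(c("d_mean", "d_median", "d_max", "d_min",
                                 "d_95", "d_1"), 2), "_",
                           rep(c("GTV", "CTV"), each = 6))) %in% names(got)))
})

test_that("a single-patient cohort reports with the comparison skipped", {
  cohort <- run_cohort(list(quiet_spec(seed = 11)))
  dir <- withr::local_tempdir()
  expect_message(make_report(cohort, tests = NULL, dir = dir), "skipped")
  expect_true(file.exists(file.path(dir, "metrics.csv")))
  expect_false(file.exists(file.path(dir, "tests.json")))
})

test_that("a failing patient is skipped while the cohort continues", {
  bad <- quiet_spec(seed = 12)
  bad$gtv_semiaxes <- c(0.1, 0.1, 0.1)       # GTV smaller than one voxel
  specs <- list(quiet_spec(seed = 13), bad)
  expect_message(cohort <- run_cohort(specs), "failed")
  expect_equal(cohort$n_patients, 1)
  expect_equal(cohort$failed, "phantom_02")
})
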