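#' Run the paired dose-painting vs uniform analysis on a synthetic cohort
#'
#' For each phantom spec: simulate the patient, build the dose-painting
#' prescription (linear cellularity-to-dose map) and the uniform
#' standard-of-care prescription, generate one synthetic plan dose per arm
#' with the *same* perturbation stream (so the arms differ only by
#' prescription), then score both arms: quality factor over GTV and CTV,
#' dose metrics per target ROI, clinical-goal table, and GTV tumour control
#' probability. A failing patient is logged and skipped; the cohort
#' continues.
#'
#' @param specs list of [phantom_spec]s (one per synthetic patient).
#' @param params [prescription_params].
#' @param radio [radiobiology_params].
#' @param goals optional named list
#'   `list(dose_painting =, uniform =)` of [clinical_goal] lists; defaults
#'   to [default_clinical_goals] per arm (missing ROIs skipped).
#' @return an object of class `cohort_result`: `metrics` (long data.frame
#'   of per-patient, per-arm values), `goal_tables`, `n_patients`,
#'   `failed` (character vector of failed patient ids).
#' @export
run_cohort <- function(specs, params = prescription_params(),
                       radio = radiobiology_params(), goals = NULL) {
  if (length(specs) < 1) stop("need at least one phantom spec")
  if (is.null(goals))
    goals <- list(dose_painting = default_clinical_goals("dose_painting"),
                  uniform = default_clinical_goals("uniform"))
  metrics <- list()
  goal_tables <- list()
  failed <- character()
  for (i in seq_along(specs)) {
    pid <- sprintf("phantom_%02d", i)
    res <- tryCatch(
      evaluate_patient(specs[[i]], params, radio, goals, pid),
      error = function(e) {
        message("patient ", pid, " failed: ", conditionMessage(e))
        NULL
      })
    if (is.null(res)) { failed <- c(failed, pid); next }
    metrics[[pid]] <- res$metrics
    goal_tables[[pid]] <- res$goals
  }
  if (length(metrics) == 0) stop("every patient in the cohort failed")
  structure(list(
    metrics = do.call(rbind, c(metrics, list(make.row.names = FALSE))),
    goal_tables = goal_tables,
    n_patients = length(metrics), failed = failed
  ), class = "cohort_result")
}

# internal: score one synthetic patient, both arms
evaluate_patient <- function(spec, params, radio, goals, pid) {
  sim <- simulate_phantom(spec, params)
  st <- sim$structures
  gtv <- gtv_mask(st); ctv <- ctv_mask(st)
  arms <- list(
    dose_painting = list(presc = sim$presc_dp, dose = sim$dose_dp),
    uniform = list(presc = sim$presc_uniform, dose = sim$dose_uniform)
  )
  rows <- list()
  gtabs <- list()
  for (arm in names(arms)) {
    presc <- arms[[arm]]$presc
    dose <- arms[[arm]]$dose
    qf_gtv <- quality_factor(dose, presc$presc, gtv)$qf
    qf_ctv <- quality_factor(dose, presc$presc, ctv)$qf
    tcp_gtv <- tcp(sim$cellularity, dose, gtv, radio)$tcp
    rec <- data.frame(patient = pid, seed = spec$seed, arm = arm,
                      QF_GTV = qf_gtv, QF_CTV = qf_ctv, TCP = tcp_gtv,
                      stringsAsFactors = FALSE)
    for (roi_name in c("GTV", "CTV")) {
      dm <- dose_metrics(dose, roi_mask(st, roi_name))
      for (f in c("d_mean", "d_median", "d_max", "d_min", "d_95", "d_1"))
        rec[[paste0(f, "_", roi_name)]] <- dm[[f]]
    }
    rows[[arm]] <- rec
    gt <- evaluate_goals(dose, st, goals[[arm]], skip_missing = TRUE)
    gt$arm <- arm
    gtabs[[arm]] <- gt
  }
  list(metrics = do.call(rbind, c(rows, list(make.row.names = FALSE))),
       goals = do.call(rbind, c(gtabs, list(make.row.names = FALSE))))
}

#' Paired Wilcoxon signed-rank test
#'
#' Two-sided matched-pairs signed-rank test on `x - y`. Zero differences
#' are dropped (Wilcoxon convention). For up to 15 nonzero pairs the exact
#' two-sided p-value is computed by enumerating all 2^m sign assignments of
#' the (tie-averaged) ranks; above that, the normal approximation with
#' continuity correction and tie correction is used. If every difference is
#' zero no test is performed and p = 1 is reported.
#'
#' @param x,y paired numeric vectors of equal length >= 5.
#' @param exact_max largest number of nonzero pairs for which the exact
#'   enumeration is used.
#' @return list with `statistic` (V, the positive-rank sum), `p_value`,
#'   `n_pairs`, `n_nonzero`, `method`.
#' @export
wilcoxon_paired <- function(x, y, exact_max = 15L) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 5) stop("need at least 5 pairs")
  d <- x - y
  d <- d[d != 0]
  m <- length(d)
  if (m == 0) {
    return(list(statistic = NA_real_, p_value = 1, n_pairs = length(x),
                n_nonzero = 0L, method = "no nonzero differences"))
  }
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  if (m <= exact_max) {
    # exact null distribution of the positive-rank sum by sign enumeration
    signs <- as.matrix(expand.grid(rep(list(c(0, 1)), m)))
    w <- as.numeric(signs %*% r)
    p <- 2 * min(mean(w <= v + 1e-9), mean(w >= v - 1e-9))
    list(statistic = v, p_value = min(p, 1), n_pairs = length(x),
         n_nonzero = m, method = "exact enumeration")
  } else {
    mu <- m * (m + 1) / 4
    ties <- table(r)
    sigma2 <- m * (m + 1) * (2 * m + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sigma2)
    list(statistic = v, p_value = min(2 * stats::pnorm(-abs(z)), 1),
         n_pairs = length(x), n_nonzero = m,
         method = "normal approximation")
  }
}

#' Holm-Sidak step-down adjusted p-values
#'
#' Step-down Sidak procedure: p-values are sorted ascending; the k-th
#' smallest is adjusted to
#' \eqn{\max_{j \le k} \big(1 - (1 - p_{(j)})^{m - j + 1}\big)}, clipped to
#' 1, and mapped back to the input order. Adjusted values are always >= the
#' raw values and monotone in the sorted order.
#'
#' @param p numeric vector of raw p-values in [0, 1].
#' @return adjusted p-values in the input order.
#' @export
holm_sidak <- function(p) {
  if (any(p < 0 | p > 1) || any(!is.finite(p)))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0) return(numeric(0))
  o <- order(p)
  adj_sorted <- cummax(pmin(1 - (1 - p[o])^(m - seq_len(m) + 1), 1))
  adj <- numeric(m)
  adj[o] <- adj_sorted
  adj
}

#' Compare the two plan arms across a cohort
#'
#' Paired Wilcoxon signed-rank tests (dose painting vs uniform) for the
#' requested metrics, with Holm-Sidak correction across the family of
#' metrics tested. Significance is flagged at adjusted p < 0.05.
#'
#' @param cohort a `cohort_result` from [run_cohort].
#' @param metrics character vector of metric column names to test.
#' @param alpha family-wise significance level.
#' @return data.frame with one row per metric: medians per arm, Wilcoxon
#'   statistic, raw and Holm-Sidak adjusted p-values, and a significance
#'   flag.
#' @export
compare_arms <- function(cohort,
                         metrics = c("QF_GTV", "QF_CTV", "TCP",
                                     "d_mean_GTV", "d_max_GTV",
                                     "d_mean_CTV", "d_max_CTV"),
                         alpha = 0.05) {
  stopifnot(inherits(cohort, "cohort_result"))
  mt <- cohort$metrics
  dp <- mt[mt$arm == "dose_painting", ]
  un <- mt[mt$arm == "uniform", ]
  dp <- dp[order(dp$patient), ]
  un <- un[order(un$patient), ]
  if (!identical(dp$patient, un$patient))
    stop("paired design broken: arms cover different patients")
  rows <- lapply(metrics, function(mname) {
    if (!mname %in% names(mt)) stop("unknown metric: ", mname)
    w <- wilcoxon_paired(dp[[mname]], un[[mname]])
    data.frame(metric = mname,
               median_dose_painting = stats::median(dp[[mname]]),
               median_uniform = stats::median(un[[mname]]),
               statistic = w$statistic, p_raw = w$p_value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adjusted <- holm_sidak(out$p_raw)
  out$significant <- out$p_adjusted < alpha
  out
}

#' Write a cohort report
#'
#' Writes the per-patient metrics as CSV, the paired-test table as JSON,
#' and box-plot figures (PNG) of the GTV/CTV dose metrics, QF and TCP by
#' plan arm. With a single patient the statistical comparison is skipped
#' with a notice.
#'
#' @param cohort a `cohort_result`.
#' @param tests optional data.frame from [compare_arms]; computed here when
#'   `NULL` and the cohort has >= 5 patients.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
make_report <- function(cohort, tests = NULL, dir) {
  stopifnot(inherits(cohort, "cohort_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()

  csv <- file.path(dir, "metrics.csv")
  utils::write.csv(cohort$metrics, csv, row.names = FALSE)
  paths <- c(paths, csv)

  if (is.null(tests)) {
    if (cohort$n_patients >= 5) {
      tests <- compare_arms(cohort)
    } else {
      message("cohort of ", cohort$n_patients,
              " patient(s): statistical comparison skipped")
    }
  }
  if (!is.null(tests)) {
    js <- file.path(dir, "tests.json")
    jsonlite::write_json(tests, js, auto_unbox = TRUE, digits = NA,
                         dataframe = "rows")
    paths <- c(paths, js)
  }

  plot_cols <- intersect(
    c("QF_GTV", "QF_CTV", "TCP", "d_mean_GTV", "d_max_GTV",
      "d_mean_CTV", "d_max_CTV"),
    names(cohort$metrics))
  for (col in plot_cols) {
    png_path <- file.path(dir, paste0("boxplot_", col, ".png"))
    grDevices::png(png_path, width = 480, height = 480)
    graphics::boxplot(
      stats::as.formula(paste(col, "~ arm")), data = cohort$metrics,
      main = col, xlab = "plan arm",
      ylab = if (col == "TCP") "probability" else
        if (startsWith(col, "QF")) "QF (%)" else "Gy(RBE)")
    grDevices::dev.off()
    paths <- c(paths, png_path)
  }
  invisible(paths)
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result> ", x$n_patients, " patient(s), 2 arms\n", sep = "")
  if (length(x$failed))
    cat("  failed: ", paste(x$failed, collapse = ", "), "\n", sep = "")
  invisible(x)
}
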