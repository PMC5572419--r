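#' Paired Wilcoxon signed-rank test
#'
#' Two-sided signed-rank test on paired per-participant means (e.g. normal
#' vs fast pace). Zero differences are dropped (classic Wilcoxon
#' convention); the exact null distribution is used for n <= 25 without
#' ties, the continuity-corrected normal approximation otherwise. When every
#' difference is zero the test is degenerate and `p = 1` is returned with a
#' warning.
#'
#' @param a,b paired numeric vectors of equal length (>= 5 recommended).
#' @param exact_max largest n (after dropping zeros) for the exact null.
#' @return a tibble with `statistic` (V), `p_value`, `n_effective`,
#'   `method`.
#' @export
paired_wilcoxon <- function(a, b, exact_max = 25L) {
  stopifnot(length(a) == length(b))
  d <- a - b
  d <- d[!is.na(d)]
  nz <- d[d != 0]
  if (!length(nz)) {
    warning("all paired differences are zero; test is degenerate",
            call. = FALSE)
    return(tibble::tibble(statistic = NA_real_, p_value = 1,
                          n_effective = 0L, method = "degenerate"))
  }
  ties <- any(duplicated(abs(nz)))
  use_exact <- length(nz) <= exact_max && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(a, b, paired = TRUE, exact = use_exact,
                       correct = TRUE))
  tibble::tibble(statistic = unname(ht$statistic), p_value = ht$p.value,
                 n_effective = length(nz),
                 method = if (use_exact) "exact" else "normal approximation")
}

#' Two-way random-effects absolute-agreement average-measures ICC
#'
#' ICC(A,k) in the McGraw-Wong convention (the "ICC(2,k)" of
#' Shrout-Fleiss): participants are random rows, trials random columns.
#' From the two-way ANOVA mean squares (rows MSR, columns MSC, error MSE),
#' `ICC = (MSR - MSE) / (MSR + (MSC - MSE) / n)`.
#' The 95% confidence interval is the F-based interval for single measures
#' stepped up to k measures (Spearman-Brown), and
#' `SEM = SD * sqrt(1 - ICC)` with SD the pooled between-participant SD of
#' the cell values.
#'
#' @param m numeric matrix, participants x trials. Rows containing missing
#'   values are dropped (listwise deletion).
#' @param conf confidence level (default 0.95).
#' @return a `turn_reliability` tibble row: `icc, ci_lo, ci_hi, sem,
#'   category, n, k, msr, msc, mse, degenerate`.
#' @export
icc_2k <- function(m, conf = 0.95) {
  m <- as.matrix(m)
  keep <- stats::complete.cases(m)
  if (any(!keep)) m <- m[keep, , drop = FALSE]
  n <- nrow(m); k <- ncol(m)
  if (n < 2L || k < 2L) {
    stop("ICC needs at least 2 participants and 2 trials after deletion",
         call. = FALSE)
  }
  grand <- mean(m)
  rm_ <- rowMeans(m)
  cm <- colMeans(m)
  ssr <- k * sum((rm_ - grand)^2)
  ssc <- n * sum((cm - grand)^2)
  sst <- sum((m - grand)^2)
  sse <- sst - ssr - ssc
  msr <- ssr / (n - 1)
  msc <- ssc / (k - 1)
  mse <- sse / ((n - 1) * (k - 1))
  if (sst < .Machine$double.eps * max(1, abs(grand))) {
    return(tibble_reliability(NA_real_, NA_real_, NA_real_, 0,
                              "degenerate", n, k, msr, msc, mse, TRUE))
  }
  icc <- (msr - mse) / (msr + (msc - mse) / n)
  # F-based interval for ICC(A,1) (McGraw & Wong 1996), stepped up to k
  alpha <- 1 - conf
  icc1 <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  aa <- k * icc1 / (n * (1 - icc1))
  bb <- 1 + k * icc1 * (n - 1) / (n * (1 - icc1))
  vv <- (aa * msc + bb * mse)^2 /
    ((aa * msc)^2 / (k - 1) + (bb * mse)^2 / ((n - 1) * (k - 1)))
  f1 <- stats::qf(1 - alpha / 2, n - 1, vv)
  lo1 <- n * (msr - f1 * mse) /
    (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
  f2 <- stats::qf(1 - alpha / 2, vv, n - 1)
  hi1 <- n * (f2 * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f2 * msr)
  step_up <- function(r1) k * r1 / (1 + (k - 1) * r1)
  sd_pooled <- stats::sd(as.numeric(m))
  sem <- sd_pooled * sqrt(max(0, 1 - icc))
  tibble_reliability(icc, step_up(lo1), step_up(hi1), sem,
                     interpret_icc(icc), n, k, msr, msc, mse, FALSE)
}

tibble_reliability <- function(icc, lo, hi, sem, category, n, k,
                               msr, msc, mse, degenerate) {
  out <- tibble::tibble(icc = icc, ci_lo = lo, ci_hi = hi, sem = sem,
                        category = category, n = n, k = k,
                        msr = msr, msc = msc, mse = mse,
                        degenerate = degenerate)
  class(out) <- c("turn_reliability", class(out))
  out
}

#' Interpret an ICC value
#'
#' Reliability bands: poor below 0.50, moderate in `[0.50, 0.75)`, good in
#' `[0.75, 0.90)`, excellent in `[0.90, 1]`. Negative ICCs are poor. The
#' half-open intervals close the gaps the verbal guidelines leave between
#' 0.50/0.51 and 0.90/0.91.
#'
#' @param icc a finite ICC estimate.
#' @return one of `"poor"`, `"moderate"`, `"good"`, `"excellent"`.
#' @export
interpret_icc <- function(icc) {
  stopifnot(is.finite(icc))
  if (icc < 0.50) "poor"
  else if (icc < 0.75) "moderate"
  else if (icc < 0.90) "good"
  else "excellent"
}

signature_metric_names <- c("H2Tmax", "D1", "D2", "t01", "t02",
                            "tbar1", "tbar2", "s1", "s2")
traditional_metric_names <- c("NbSteps", "turnvel_mean", "turnvel_max")

#' Pace (velocity) effect report
#'
#' For each metric, averages the repeated trials per participant and pace,
#' then compares normal vs fast with the paired Wilcoxon signed-rank test.
#' Only participants with both paces contribute to the test.
#'
#' @param metrics per-trial metrics tibble (from [compute_signature()] /
#'   [read_metrics_table()]); rows with `qc_pass == FALSE` are dropped
#'   first.
#' @param metric_names metrics to report (default: all signature and
#'   traditional metrics present).
#' @param alpha significance level annotated in the output.
#' @return a tibble with one row per metric: per-pace mean and SD across
#'   participants, `p_value` and `significant`.
#' @export
velocity_effect_report <- function(metrics,
                                   metric_names = NULL,
                                   alpha = 0.05) {
  metrics <- dplyr::filter(metrics, .data$qc_pass | is.na(.data$qc_pass))
  if (is.null(metric_names)) {
    metric_names <- intersect(c(signature_metric_names,
                                traditional_metric_names), names(metrics))
    metric_names <- metric_names[vapply(metric_names, function(nm) {
      !all(is.na(metrics[[nm]]))
    }, logical(1))]
  }
  purrr::map_dfr(metric_names, function(nm) {
    per <- metrics |>
      dplyr::group_by(.data$participant_id, .data$pace) |>
      dplyr::summarise(value = mean(.data[[nm]], na.rm = TRUE),
                       .groups = "drop") |>
      tidyr::pivot_wider(names_from = "pace", values_from = "value")
    for (p in c("normal", "fast")) if (!p %in% names(per)) per[[p]] <- NA_real_
    paired <- per[stats::complete.cases(per[, c("normal", "fast")]), ]
    wt <- if (nrow(paired) >= 2L) {
      paired_wilcoxon(paired$normal, paired$fast)
    } else {
      tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                     n_effective = 0L, method = "insufficient pairs")
    }
    tibble::tibble(
      metric = nm,
      mean_normal = mean(per$normal, na.rm = TRUE),
      sd_normal = stats::sd(per$normal[!is.na(per$normal)]),
      mean_fast = mean(per$fast, na.rm = TRUE),
      sd_fast = stats::sd(per$fast[!is.na(per$fast)]),
      n_pairs = nrow(paired),
      p_value = wt$p_value,
      significant = !is.na(wt$p_value) & wt$p_value < alpha
    )
  })
}

#' Test-retest reliability report over repeated trials
#'
#' Builds the participants x trials matrix of each metric (trials ordered
#' `normal1, normal2, fast1, fast2, ...` by pace then trial id), applies
#' listwise deletion, and computes ICC(A,k), its 95% CI, SEM and the
#' interpretation band, plus the normal-vs-fast Wilcoxon p.
#'
#' @inheritParams velocity_effect_report
#' @return a tibble with one row per metric: `icc, ci_lo, ci_hi, sem,
#'   category, n, k, wilcoxon_p`.
#' @export
reliability_report <- function(metrics, metric_names = NULL) {
  metrics <- dplyr::filter(metrics, .data$qc_pass | is.na(.data$qc_pass))
  if (is.null(metric_names)) {
    metric_names <- intersect(c(signature_metric_names,
                                traditional_metric_names), names(metrics))
    metric_names <- metric_names[vapply(metric_names, function(nm) {
      !all(is.na(metrics[[nm]]))
    }, logical(1))]
  }
  ve <- velocity_effect_report(metrics, metric_names)
  purrr::map_dfr(metric_names, function(nm) {
    wide <- metrics |>
      dplyr::arrange(.data$pace, .data$trial_id) |>
      dplyr::group_by(.data$participant_id, .data$pace) |>
      dplyr::mutate(slot = paste0(.data$pace, dplyr::row_number())) |>
      dplyr::ungroup() |>
      dplyr::select("participant_id", "slot", value = dplyr::all_of(nm)) |>
      tidyr::pivot_wider(names_from = "slot", values_from = "value")
    m <- as.matrix(wide[, -1, drop = FALSE])
    rel <- tryCatch(icc_2k(m), error = function(e) {
      tibble_reliability(NA_real_, NA_real_, NA_real_, NA_real_,
                         "degenerate", nrow(m), ncol(m),
                         NA_real_, NA_real_, NA_real_, TRUE)
    })
    tibble::tibble(
      metric = nm, icc = rel$icc, ci_lo = rel$ci_lo, ci_hi = rel$ci_hi,
      sem = rel$sem, category = rel$category, n = rel$n, k = rel$k,
      wilcoxon_p = ve$p_value[ve$metric == nm]
    )
  })
}
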