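#' Shrout-Fleiss intraclass correlation with exact F-based 95% CI
#'
#' Single-measure intraclass correlation coefficients computed from ANOVA
#' mean squares of a complete subjects-by-raters table, in the three
#' classical single-rating forms:
#'
#' * `ICC_1_1` — one-way random: each subject rated by a different set of
#'   raters; `(MSB - MSW) / (MSB + (k-1) MSW)`.
#' * `ICC_2_1` — two-way random, absolute agreement (the default here for
#'   repeatability/reproducibility designs, where scans/observers are a
#'   random draw from possible acquisitions);
#'   `(MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' * `ICC_3_1` — two-way mixed, consistency: rater offsets excluded;
#'   `(MSR - MSE) / (MSR + (k-1) MSE)`.
#'
#' Confidence bounds use the exact F intervals for forms 1 and 3 and the
#' Satterthwaite-approximated F interval for form 2.
#'
#' @param table a long data frame with columns `participant_id`,
#'   `rater_id`, `value` (one row per rating, complete design), or a
#'   numeric subjects-by-raters matrix.
#' @param model `"ICC_2_1"` (default), `"ICC_1_1"` or `"ICC_3_1"`.
#' @param conf_level confidence level for the interval, default 0.95.
#' @return an `icc_result`: `estimate`, `ci_low`, `ci_high`, `model`,
#'   `label` (Cicchetti class), `n_subjects`, `k_raters`, and
#'   `mean_squares` (`between_subjects`, `between_raters`, `residual`,
#'   `within_subjects`).
#' @export
icc <- function(table, model = c("ICC_2_1", "ICC_1_1", "ICC_3_1"),
                conf_level = 0.95) {
  model <- match.arg(model)
  Y <- pivot_measurements(table)
  n <- nrow(Y); k <- ncol(Y)
  if (n < 2L || k < 2L)
    stop_input("need at least 2 subjects and 2 raters")
  if (anyNA(Y)) stop_input("incomplete design: missing cells")
  if (stats::var(as.vector(Y)) == 0)
    stop_input("degenerate input: zero total variance")
  grand <- mean(Y)
  rowm <- rowMeans(Y); colm <- colMeans(Y)
  MSR <- k * sum((rowm - grand)^2) / (n - 1)          # between subjects
  MSC <- n * sum((colm - grand)^2) / (k - 1)          # between raters
  MSE <- sum((Y - outer(rowm, rep(1, k)) - outer(rep(1, n), colm) +
                grand)^2) / ((n - 1) * (k - 1))       # residual
  MSW <- sum((Y - rowm)^2) / (n * (k - 1))            # within subjects
  alpha <- 1 - conf_level

  if (model == "ICC_1_1") {
    est <- (MSR - MSW) / (MSR + (k - 1) * MSW)
    Fobs <- MSR / MSW
    FL <- Fobs / qf(1 - alpha / 2, n - 1, n * (k - 1))
    FU <- Fobs * qf(1 - alpha / 2, n * (k - 1), n - 1)
    lo <- (FL - 1) / (FL + k - 1)
    hi <- (FU - 1) / (FU + k - 1)
  } else if (model == "ICC_3_1") {
    est <- (MSR - MSE) / (MSR + (k - 1) * MSE)
    Fobs <- MSR / MSE
    FL <- Fobs / qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    FU <- Fobs * qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    lo <- (FL - 1) / (FL + k - 1)
    hi <- (FU - 1) / (FU + k - 1)
  } else {
    est <- (MSR - MSE) / (MSR + (k - 1) * MSE + k * (MSC - MSE) / n)
    # Satterthwaite df for the rater + residual composite (Shrout & Fleiss)
    a <- k * est / (n * (1 - est))
    b <- 1 + k * est * (n - 1) / (n * (1 - est))
    v <- (a * MSC + b * MSE)^2 /
      ((a * MSC)^2 / (k - 1) + (b * MSE)^2 / ((n - 1) * (k - 1)))
    Fstar_lo <- qf(1 - alpha / 2, n - 1, v)
    Fstar_hi <- qf(1 - alpha / 2, v, n - 1)
    lo <- n * (MSR - Fstar_lo * MSE) /
      (Fstar_lo * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
    hi <- n * (Fstar_hi * MSR - MSE) /
      (k * MSC + (k * n - k - n) * MSE + n * Fstar_hi * MSR)
  }
  # perfect-agreement tables (MSE or MSW exactly 0) make the F intervals
  # ill-defined; collapse the CI onto the point estimate
  if (!is.finite(lo)) lo <- est
  if (!is.finite(hi)) hi <- est
  lo <- max(-1, min(lo, est))
  hi <- min(1, max(hi, est))
  structure(list(estimate = est, ci_low = lo, ci_high = hi, model = model,
                 label = cicchetti_label(max(-1, min(1, est))),
                 n_subjects = n, k_raters = k,
                 mean_squares = list(between_subjects = MSR,
                                     between_raters = MSC,
                                     residual = MSE,
                                     within_subjects = MSW)),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("%s = %.3f (95%% CI, %.3f-%.3f), %s; n = %d subjects x %d raters\n",
              gsub("_", ",", sub("ICC_", "ICC(", x$model)) |> paste0(")"),
              x$estimate, x$ci_low, x$ci_high, x$label,
              x$n_subjects, x$k_raters))
  invisible(x)
}

# long data frame (participant_id, rater_id, value) -> subjects x raters
pivot_measurements <- function(table) {
  if (is.matrix(table)) {
    Y <- table
    storage.mode(Y) <- "double"
    return(Y)
  }
  if (!is.data.frame(table) ||
      !all(c("participant_id", "rater_id", "value") %in% names(table)))
    stop_input("table must have columns participant_id, rater_id, value")
  subj <- unique(table$participant_id)
  raters <- unique(table$rater_id)
  Y <- matrix(NA_real_, length(subj), length(raters),
              dimnames = list(as.character(subj), as.character(raters)))
  Y[cbind(match(table$participant_id, subj),
          match(table$rater_id, raters))] <- table$value
  if (anyNA(Y)) stop_input("incomplete design: missing cells")
  Y
}

#' Coefficient of variation of repeated measurements
#'
#' Per-subject coefficient of variation, `SD / mean x 100` (sample SD,
#' n-1), averaged across subjects (`"pooled_per_subject_mean"`, default) or
#' computed once on the flattened series (`"overall"`).
#'
#' @param values_per_subject a list of numeric vectors (one per subject,
#'   each of length >= 2) or a subjects-by-repeats matrix.
#' @param aggregation `"pooled_per_subject_mean"` or `"overall"`.
#' @return a `cv_result`: `cv_percent`, `aggregation`, `per_subject`.
#' @export
cv <- function(values_per_subject,
               aggregation = c("pooled_per_subject_mean", "overall")) {
  aggregation <- match.arg(aggregation)
  if (is.matrix(values_per_subject))
    values_per_subject <- split(values_per_subject,
                                row(values_per_subject))
  if (!is.list(values_per_subject) || length(values_per_subject) == 0L)
    stop_input("values_per_subject must be a non-empty list or matrix")
  if (any(vapply(values_per_subject, length, 1L) < 2L))
    stop_input("every subject needs at least 2 repeated values")
  means <- vapply(values_per_subject, mean, 1)
  if (any(means <= 0)) stop_input("all subject means must be positive")
  per <- vapply(values_per_subject, function(v) sd(v) / mean(v) * 100, 1)
  cvp <- if (aggregation == "pooled_per_subject_mean") {
    mean(per)
  } else {
    all <- unlist(values_per_subject)
    sd(all) / mean(all) * 100
  }
  structure(list(cv_percent = cvp, aggregation = aggregation,
                 per_subject = unname(per)),
            class = "cv_result")
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean of the paired differences `x - y`), sample SD of the
#' differences, and the 95% limits of agreement `bias +/- 1.96 SD`; the
#' per-subject `(mean, difference)` coordinates are returned for plotting.
#'
#' @param x,y paired measurement series of equal length >= 3.
#' @return a `bland_altman_result`: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `pairs` (data frame with `mean`, `difference`).
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop_input("x and y must have equal length")
  if (length(x) < 3L) stop_input("need at least 3 pairs")
  d <- x - y
  bias <- mean(d); s <- sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 pairs = data.frame(mean = (x + y) / 2, difference = d)),
            class = "bland_altman_result")
}

#' Paired Student t-test
#'
#' Two-sided paired t-test on the differences `x - y`, with
#' `t = mean(d) / (sd(d) / sqrt(n))` and p from the t distribution with
#' `n - 1` degrees of freedom.
#'
#' @param x,y paired series, equal length >= 2, with non-constant
#'   differences.
#' @return list with `t`, `p`, `df`, `mean_difference`.
#' @export
paired_t <- function(x, y) {
  if (length(x) != length(y)) stop_input("x and y must have equal length")
  n <- length(x)
  if (n < 2L) stop_input("need at least 2 pairs")
  d <- x - y
  s <- sd(d)
  if (s == 0) stop_input("degenerate input: zero variance of differences")
  t <- mean(d) / (s / sqrt(n))
  list(t = t, p = 2 * pt(-abs(t), n - 1), df = n - 1, mean_difference = mean(d))
}

#' Shapiro-Wilk normality check
#'
#' Standard Shapiro-Wilk test (delegated to [stats::shapiro.test()]),
#' valid for 3 <= n <= 5000 non-constant samples.
#'
#' @param values numeric series.
#' @return list with `W` and `p`.
#' @export
normality_check <- function(values) {
  n <- length(values)
  if (n < 3L || n > 5000L) stop_input("Shapiro-Wilk requires 3 <= n <= 5000")
  if (sd(values) == 0) stop_input("degenerate input: constant series")
  sw <- shapiro.test(values)
  list(W = unname(sw$statistic), p = sw$p.value)
}

#' Cicchetti clinical-significance label for a reliability coefficient
#'
#' Bands: below 0.40 poor; 0.40-0.59 fair; 0.60-0.74 good; 0.75-1.00
#' excellent (boundaries belong to the upper band).
#'
#' @param icc_estimate numeric in \[-1, 1\] (vectorised).
#' @return character vector of labels.
#' @export
cicchetti_label <- function(icc_estimate) {
  if (any(icc_estimate < -1 | icc_estimate > 1))
    stop_input("estimate must lie in [-1, 1]")
  as.character(cut(icc_estimate, c(-1, 0.40, 0.60, 0.75, 1),
                   labels = c("poor", "fair", "good", "excellent"),
                   right = FALSE, include.lowest = TRUE))
}

#' Descriptive summary "mean +/- SD (range)"
#'
#' @param values numeric series of length >= 2.
#' @param digits decimals in the formatted string (3 for fractal
#'   dimensions, 1-2 for demographics).
#' @return list with `mean`, `sd` (sample, n-1), `min`, `max`, `formatted`.
#' @export
summarize_values <- function(values, digits = 3) {
  if (length(values) < 2L) stop_input("need at least 2 values")
  m <- mean(values); s <- sd(values)
  fmt <- function(v) formatC(v, digits = digits, format = "f")
  structure(list(mean = m, sd = s, min = min(values), max = max(values),
                 formatted = sprintf("%s ± %s (%s-%s)", fmt(m), fmt(s),
                                     fmt(min(values)), fmt(max(values)))),
            class = "summary_values")
}

#' Categorical summary "n (percent)"
#'
#' @param count numerator.
#' @param total denominator (> 0).
#' @param digits decimals for the percentage, default 2.
#' @return list with `count`, `total`, `percent`, `formatted` such as
#'   `"29 (67.44)"`.
#' @export
format_count_percent <- function(count, total, digits = 2) {
  if (total <= 0) stop_input("total must be positive")
  pct <- 100 * count / total
  list(count = count, total = total, percent = pct,
       formatted = sprintf("%d (%s)", as.integer(count),
                           formatC(pct, digits = digits, format = "f")))
}
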