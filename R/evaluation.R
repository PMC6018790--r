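#' @title Validation splits, accuracy metrics and group comparisons
#' @description Centre-based external / 3:1 internal split, the 20-percent-band
#'   ideal-prediction classification, MAE/RMSE, dose-subgroup breakdowns and
#'   the between-group t and chi-square comparisons.
#' @name evaluation
NULL

#' Split specification
#'
#' @param center_size_threshold Centres enrolling fewer than this many cases
#'   form the external validation group (default 200).
#' @param train_ratio Fraction of the remaining rows assigned to training
#'   (default 0.75, i.e. a 3:1 split).
#' @param seed Seed for the random permutation.
#' @return Object of class `split_spec`.
#' @export
split_spec <- function(center_size_threshold = 200, train_ratio = 0.75, seed = 1L) {
  if (center_size_threshold < 1) stop_invalid("split_spec: threshold must be >= 1")
  if (train_ratio <= 0 || train_ratio >= 1) stop_invalid("split_spec: train_ratio must be in (0, 1)")
  structure(list(center_size_threshold = as.integer(center_size_threshold),
                 train_ratio = train_ratio, seed = as.integer(seed)),
            class = "split_spec")
}

#' Partition a cohort into training / internal / external groups
#'
#' All rows from centres enrolling fewer than `center_size_threshold` cases
#' form the external group; the remaining rows are randomly permuted and
#' split so that `round(train_ratio * n)` go to training and the rest to
#' internal validation. The three groups partition the cohort exactly.
#'
#' @param cohort Data.frame with a `center_id` column.
#' @param spec A [split_spec()].
#' @return List with data.frames `train`, `internal`, `external`.
#' @export
split_dataset <- function(cohort, spec = split_spec()) {
  if (!"center_id" %in% names(cohort)) stop_invalid("split_dataset: cohort lacks center_id")
  sizes <- table(cohort$center_id)
  small <- names(sizes)[sizes < spec$center_size_threshold]
  if (length(small) == 0) {
    warning("split_dataset: no centre below the threshold; external group is empty")
  }
  ext_idx <- which(cohort$center_id %in% small)
  rest_idx <- setdiff(seq_len(nrow(cohort)), ext_idx)
  if (length(rest_idx) < 2) stop_invalid("split_dataset: fewer than 2 rows left to split 3:1")
  perm <- with_seed(spec$seed, sample(rest_idx))
  n_train <- round(spec$train_ratio * length(perm))
  list(train = cohort[perm[seq_len(n_train)], , drop = FALSE],
       internal = cohort[perm[-seq_len(n_train)], , drop = FALSE],
       external = cohort[ext_idx, , drop = FALSE])
}

#' Classify a prediction against the 20% band
#'
#' `ideal` iff |pred - actual| <= 0.2 * actual (boundary inclusive);
#' otherwise `underestimate` when pred < actual, else `overestimate`.
#'
#' @param pred Predicted dose(s), mg/d.
#' @param actual Actual dose(s), mg/d; must be > 0.
#' @return Character vector in {underestimate, ideal, overestimate}.
#' @export
classify_prediction <- function(pred, actual) {
  if (any(!is.finite(actual)) || any(actual <= 0)) {
    stop_invalid("classify_prediction: actual dose must be finite and > 0")
  }
  ifelse(abs(pred - actual) <= 0.2 * actual, "ideal",
         ifelse(pred < actual, "underestimate", "overestimate"))
}

#' Dose subgroup of an actual dose
#'
#' low < 2.5 mg/d, intermediate in the closed interval \[2.5, 3.0\],
#' high > 3.0 mg/d.
#'
#' @param actual Actual dose(s), mg/d; must be > 0.
#' @return Character vector in {low, intermediate, high}.
#' @export
dose_subgroup <- function(actual) {
  if (any(!is.finite(actual)) || any(actual <= 0)) {
    stop_invalid("dose_subgroup: actual dose must be finite and > 0")
  }
  ifelse(actual < 2.5, "low", ifelse(actual > 3.0, "high", "intermediate"))
}

count_classes <- function(classes) {
  lv <- c("underestimate", "ideal", "overestimate")
  cnt <- vapply(lv, function(l) sum(classes == l), integer(1))
  pct <- if (length(classes) > 0) round_half_out(100 * cnt / length(classes), 1) else cnt * NA_real_
  list(n = length(classes), counts = cnt, percentages = pct)
}

#' Accuracy report for a set of predictions
#'
#' MAE, RMSE, and underestimate/ideal/overestimate counts and percentages
#' (1 decimal place, half away from zero), overall and within the low /
#' intermediate / high dose subgroups.
#'
#' @param preds Predicted doses, mg/d.
#' @param actuals Actual doses, mg/d.
#' @return Object of class `accuracy_report`.
#' @export
accuracy_report <- function(preds, actuals) {
  if (length(preds) != length(actuals)) stop_invalid("accuracy_report: length mismatch")
  if (length(preds) == 0) stop_invalid("accuracy_report: empty input")
  err <- preds - actuals
  classes <- classify_prediction(preds, actuals)
  sub <- dose_subgroup(actuals)
  subgroups <- lapply(c(low = "low", intermediate = "intermediate", high = "high"),
                      function(s) count_classes(classes[sub == s]))
  structure(c(count_classes(classes),
              list(mae = mean(abs(err)), rmse = sqrt(mean(err^2)),
                   subgroups = subgroups, abs_errors = abs(err))),
            class = "accuracy_report")
}

#' @export
print.accuracy_report <- function(x, ...) {
  cat(sprintf("Accuracy report (n = %d)\n", x$n))
  cat(sprintf("  MAE  %.3f mg/d\n  RMSE %.3f mg/d\n", x$mae, x$rmse))
  row <- function(lab, cc) {
    cat(sprintf("  %-14s Under %5d (%5.1f)  Ideal %5d (%5.1f)  Over %5d (%5.1f)\n",
                lab, cc$counts[1], cc$percentages[1], cc$counts[2], cc$percentages[2],
                cc$counts[3], cc$percentages[3]))
  }
  row("total", x)
  for (s in names(x$subgroups)) if (x$subgroups[[s]]$n > 0) row(s, x$subgroups[[s]])
  invisible(x)
}

#' Percentile bootstrap CI for the MAE
#'
#' Convenience interval mirroring the parenthesised ranges of published
#' accuracy tables; the published interval method is unstated, so this is a
#' plain percentile bootstrap and not an acceptance surface.
#'
#' @param abs_errors Per-patient absolute errors, mg/d.
#' @param level Confidence level. @param n_boot Bootstrap replicates.
#' @param seed Seed.
#' @return Length-2 vector (lower, upper).
#' @export
bootstrap_mae_ci <- function(abs_errors, level = 0.95, n_boot = 1000, seed = 1L) {
  with_seed(seed, {
    reps <- vapply(seq_len(n_boot), function(i) {
      mean(sample(abs_errors, length(abs_errors), replace = TRUE))
    }, numeric(1))
    unname(stats::quantile(reps, c((1 - level) / 2, 1 - (1 - level) / 2)))
  })
}

#' Compare two validation groups
#'
#' Independent-samples t-test (Welch by default) on the per-patient absolute
#' errors and a 2x2 chi-square test (ideal vs not ideal, no continuity
#' correction by default) on the classification counts, both two-sided.
#'
#' @param report_a,report_b `accuracy_report`s of the two groups.
#' @param abs_errors_a,abs_errors_b Per-patient absolute errors (defaults:
#'   taken from the reports).
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @param correct Apply Yates continuity correction to the chi-square.
#' @return List with `t` (statistic, df, p_value) and `chisq`
#'   (statistic, df, p_value).
#' @export
compare_groups <- function(report_a, report_b,
                           abs_errors_a = report_a$abs_errors,
                           abs_errors_b = report_b$abs_errors,
                           var_equal = FALSE, correct = FALSE) {
  if (length(abs_errors_a) == 0 || length(abs_errors_b) == 0) {
    stop_invalid("compare_groups: both groups must be nonempty")
  }
  const_a <- length(abs_errors_a) == 1 || stats::var(abs_errors_a) == 0
  const_b <- length(abs_errors_b) == 1 || stats::var(abs_errors_b) == 0
  tt <- if (const_a && const_b) {
    if (mean(abs_errors_a) == mean(abs_errors_b)) {
      list(statistic = 0, parameter = NA_real_, p.value = 1)
    } else {
      stop_invalid("compare_groups: both groups degenerate; t-test undefined")
    }
  } else {
    stats::t.test(abs_errors_a, abs_errors_b, var.equal = var_equal)
  }
  m <- rbind(c(report_a$counts[["ideal"]], report_a$n - report_a$counts[["ideal"]]),
             c(report_b$counts[["ideal"]], report_b$n - report_b$counts[["ideal"]]))
  cs <- suppressWarnings(stats::chisq.test(m, correct = correct))
  list(t = list(statistic = unname(tt$statistic), df = unname(tt$parameter),
                p_value = tt$p.value),
       chisq = list(statistic = unname(cs$statistic), df = unname(cs$parameter),
                    p_value = cs$p.value))
}
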