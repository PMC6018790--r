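#' @title Variable selection and feature scaling
#' @description Two-step input-variable selection — completeness (integrity)
#'   filtering and an ANCOVA partial eta-squared screen with
#'   mandatory-variable enrollment — plus min–max scaling for the network.
#' @name preprocess_select
NULL

#' Selection configuration
#'
#' @param integrity_threshold Columns whose non-missing fraction is strictly
#'   below this are dropped (default 0.50).
#' @param eta2_threshold Minimum partial eta-squared to survive the screen.
#'   Default 0.001, matching the published screen that retained variables at
#'   eta^2 = 0.001; 0.01 is the stricter alternative.
#' @param alpha Significance level for the per-effect F test.
#' @param mandatory Variables enrolled regardless of the screen.
#' @return An object of class `selection_config`.
#' @export
selection_config <- function(integrity_threshold = 0.50,
                             eta2_threshold = 0.001,
                             alpha = 0.05,
                             mandatory = c("height", "weight")) {
  if (integrity_threshold <= 0 || integrity_threshold >= 1 ||
      eta2_threshold <= 0 || eta2_threshold >= 1 ||
      alpha <= 0 || alpha >= 1) {
    stop_invalid("selection_config: thresholds must lie in (0, 1)")
  }
  if (anyDuplicated(mandatory)) stop_invalid("selection_config: mandatory names must be distinct")
  structure(list(integrity_threshold = integrity_threshold,
                 eta2_threshold = eta2_threshold,
                 alpha = alpha, mandatory = mandatory),
            class = "selection_config")
}

#' Drop columns with insufficient completeness
#'
#' Removes every column whose non-missing fraction is strictly below
#' `threshold`; rows are never dropped. Idempotent.
#'
#' @param table A data.frame.
#' @param threshold Completeness threshold in (0, 1].
#' @return A list with `table` (reduced) and `dropped` (data.frame of column
#'   name and completeness for each removed column).
#' @export
filter_integrity <- function(table, threshold = 0.50) {
  if (!is.data.frame(table) || nrow(table) == 0 || ncol(table) == 0) {
    stop_invalid("filter_integrity: table must be a non-empty data.frame")
  }
  completeness <- vapply(table, function(col) mean(!is.na(col)), numeric(1))
  drop <- completeness < threshold
  list(table = table[, !drop, drop = FALSE],
       dropped = data.frame(name = names(table)[drop],
                            completeness = unname(completeness[drop]),
                            stringsAsFactors = FALSE))
}

#' ANCOVA partial eta-squared screen
#'
#' Fits a single linear model of the outcome on all candidates and computes,
#' per candidate, the Type I (sequential) sum of squares in the given order.
#' Partial eta-squared is `SS_effect / (SS_effect + SS_error)` with the
#' model's residual SS as error; each effect gets an F-test p-value.
#' Rows with missing values in any used column are dropped (complete-case).
#' Constant or collinear candidates are flagged with eta^2 = 0 and p = 1.
#'
#' @param table Data.frame holding outcome and candidates.
#' @param outcome Name of the continuous outcome column.
#' @param candidates Character vector of candidate variable names.
#' @param order Sequence in which candidates enter the sequential
#'   decomposition (default: `candidates` as given).
#' @return Data.frame with columns `name`, `partial_eta2`, `p_value`,
#'   `flagged`, one row per candidate in `order`.
#' @export
ancova_partial_eta2 <- function(table, outcome, candidates, order = candidates) {
  if (!outcome %in% names(table)) stop_invalid("ancova_partial_eta2: outcome not in table")
  if (!all(candidates %in% names(table))) {
    stop_invalid("ancova_partial_eta2: candidates missing from table: ",
                 paste(setdiff(candidates, names(table)), collapse = ", "))
  }
  if (!setequal(order, candidates)) {
    stop_invalid("ancova_partial_eta2: order must be a permutation of candidates")
  }
  used <- table[, c(outcome, order), drop = FALSE]
  used <- used[stats::complete.cases(used), , drop = FALSE]
  if (nrow(used) <= length(order) + 1) {
    stop_invalid("ancova_partial_eta2: too few complete cases for the model")
  }
  fml <- stats::as.formula(paste(outcome, "~", paste(order, collapse = " + ")))
  fit <- stats::lm(fml, data = used)
  tab <- stats::anova(fit)
  ss_err <- tab["Residuals", "Sum Sq"]
  res <- data.frame(name = order, partial_eta2 = NA_real_, p_value = NA_real_,
                    flagged = FALSE, stringsAsFactors = FALSE)
  for (i in seq_along(order)) {
    v <- order[i]
    if (v %in% rownames(tab) && is.finite(tab[v, "Sum Sq"])) {
      ss <- tab[v, "Sum Sq"]
      res$partial_eta2[i] <- ss / (ss + ss_err)
      p <- tab[v, "Pr(>F)"]
      res$p_value[i] <- if (is.finite(p)) p else 1
    } else {
      warning("ancova_partial_eta2: candidate '", v,
              "' is constant or collinear; flagged with eta2 = 0, p = 1")
      res$partial_eta2[i] <- 0
      res$p_value[i] <- 1
      res$flagged[i] <- TRUE
    }
  }
  res
}

#' Apply the screen thresholds and enroll mandatory variables
#'
#' Keeps candidates with `partial_eta2 >= eta2_threshold` and
#' `p_value < alpha`, in screen order, then appends mandatory variables not
#' already present.
#'
#' @param scores Data.frame as returned by [ancova_partial_eta2()].
#' @param config A [selection_config()].
#' @return Character vector of selected variable names.
#' @export
select_variables <- function(scores, config = selection_config()) {
  if ((is.null(scores) || nrow(scores) == 0) && length(config$mandatory) == 0) {
    stop_invalid("select_variables: no candidates and no mandatory variables")
  }
  kept <- character(0)
  if (!is.null(scores) && nrow(scores) > 0) {
    keep <- scores$partial_eta2 >= config$eta2_threshold & scores$p_value < config$alpha
    kept <- scores$name[keep]
  }
  out <- c(kept, setdiff(config$mandatory, kept))
  if (length(out) == 0) stop_invalid("select_variables: selection is empty")
  out
}

#' Fit a min–max scaler
#'
#' Learns per-feature minimum and range on the training table so each listed
#' variable maps to \[0, 1\]. Zero-range features are mapped to constant 0
#' with a warning. The fitted scaler is reusable on validation tables (where
#' values may fall outside \[0, 1\]) and invertible.
#'
#' @param table Training data.frame (no missing values in `vars`).
#' @param vars Variables to scale.
#' @return Object of class `minmax_scaler`.
#' @export
fit_minmax <- function(table, vars) {
  if (!all(vars %in% names(table))) {
    stop_invalid("fit_minmax: variables missing from table: ",
                 paste(setdiff(vars, names(table)), collapse = ", "))
  }
  mins <- vapply(vars, function(v) min(table[[v]]), numeric(1))
  maxs <- vapply(vars, function(v) max(table[[v]]), numeric(1))
  ranges <- maxs - mins
  if (any(ranges == 0)) {
    warning("fit_minmax: zero-range feature(s) scaled to constant 0: ",
            paste(vars[ranges == 0], collapse = ", "))
  }
  structure(list(vars = vars, mins = mins, ranges = ranges),
            class = "minmax_scaler")
}

#' Apply a fitted min–max scaler
#'
#' @param scaler A `minmax_scaler`.
#' @param table Data.frame containing the scaler's variables.
#' @param vars Subset of the scaler's variables to produce (default all).
#' @return Numeric matrix, one column per variable.
#' @export
apply_minmax <- function(scaler, table, vars = scaler$vars) {
  if (!all(vars %in% scaler$vars)) stop_invalid("apply_minmax: unknown variables")
  out <- vapply(vars, function(v) {
    if (scaler$ranges[[v]] == 0) rep(0, nrow(table))
    else (table[[v]] - scaler$mins[[v]]) / scaler$ranges[[v]]
  }, numeric(nrow(table)))
  out <- matrix(out, nrow = nrow(table), dimnames = list(NULL, vars))
  out
}

#' Invert a min–max scaling
#'
#' @param scaler A `minmax_scaler`.
#' @param values Scaled values (vector or matrix with named columns).
#' @param var Variable name the values belong to (required for vectors).
#' @return Values on the original scale.
#' @export
invert_minmax <- function(scaler, values, var) {
  if (!var %in% scaler$vars) stop_invalid("invert_minmax: unknown variable ", var)
  values * scaler$ranges[[var]] + scaler$mins[[var]]
}

#' Serialize a scaler to JSON
#' @param scaler A `minmax_scaler`.
#' @param path File to write.
#' @return The path, invisibly.
#' @export
write_scaler <- function(scaler, path) {
  jsonlite::write_json(list(vars = scaler$vars,
                            mins = as.list(scaler$mins),
                            ranges = as.list(scaler$ranges)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a scaler back from JSON
#' @param path File written by [write_scaler()].
#' @return A `minmax_scaler`.
#' @export
read_scaler <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(vars = x$vars, mins = unlist(x$mins), ranges = unlist(x$ranges)),
            class = "minmax_scaler")
}
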