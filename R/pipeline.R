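#' @title End-to-end pipeline, configuration and cohort IO
#' @description Ties the stages together — simulate (or load) a cohort,
#'   integrity filter, ANCOVA screen with mandatory enrollment, centre-based
#'   split, hidden-size search, GA weight search, back-propagation, and
#'   internal/external validation — with a single master seed fanned out
#'   deterministically to every stochastic stage.
#' @name cli_io
NULL

#' Read a cohort CSV
#'
#' Validates the documented schema (all cohort columns present, numeric
#' columns numeric); empty fields become missing values. Parse errors name
#' the offending column and row.
#'
#' @param path CSV file.
#' @return Cohort data.frame.
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_invalid("read_cohort: no such file: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character",
                         na.strings = "")
  missing_cols <- setdiff(.cohort_columns, names(raw))
  if (length(missing_cols) > 0) {
    stop_invalid("read_cohort: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(raw), .cohort_columns)
  if (length(extra) > 0) {
    stop_invalid("read_cohort: unknown column(s): ", paste(extra, collapse = ", "))
  }
  for (v in setdiff(.cohort_columns, "center_id")) {
    parsed <- suppressWarnings(as.numeric(raw[[v]]))
    bad <- which(is.na(parsed) & !is.na(raw[[v]]))
    if (length(bad) > 0) {
      stop_invalid("read_cohort: non-numeric value '", raw[[v]][bad[1]],
                   "' in column '", v, "' at row ", bad[1])
    }
    raw[[v]] <- parsed
  }
  raw[, .cohort_columns]
}

#' Write a cohort CSV
#'
#' Missing values are written as empty fields; read/write round trips are
#' lossless.
#'
#' @param table Cohort data.frame.
#' @param path Destination file.
#' @return The path, invisibly.
#' @export
write_cohort <- function(table, path) {
  missing_cols <- setdiff(.cohort_columns, names(table))
  if (length(missing_cols) > 0) {
    stop_invalid("write_cohort: missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  utils::write.csv(table[, .cohort_columns], path, row.names = FALSE, na = "")
  invisible(path)
}

#' Pipeline configuration
#'
#' @param cohort A [cohort_config()], or a path to a cohort CSV to load
#'   instead of simulating.
#' @param selection A [selection_config()].
#' @param split A [split_spec()] (its seed is overridden by the master seed
#'   fan-out).
#' @param ga A [ga_config()] (seed likewise derived), or `NULL` to train
#'   from a random initialisation.
#' @param train A [train_config()].
#' @param hidden `"search"` to run the hidden-size search, or a fixed
#'   integer hidden-layer size.
#' @param alpha_range Alphas for the hidden-size search.
#' @param candidates Candidate variables offered to the ANCOVA screen.
#' @param seed Master seed fanned out deterministically to each stage.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(cohort = cohort_config(),
                            selection = selection_config(),
                            split = split_spec(),
                            ga = ga_config(),
                            train = train_config(),
                            hidden = "search",
                            alpha_range = 1:10,
                            candidates = c("age", "ef", "lvdd", "operation_history",
                                           "albumin", "urea_nitrogen", "creatinine",
                                           "aptt_preop", "first_anticoagulant_day",
                                           "warfarin_origin"),
                            seed = 42L) {
  structure(list(cohort = cohort, selection = selection, split = split,
                 ga = ga, train = train, hidden = hidden,
                 alpha_range = alpha_range, candidates = candidates,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Build a pipeline configuration from a YAML file
#'
#' Recognised top-level keys mirror the [pipeline_config()] arguments; each
#' sub-config is a mapping of that constructor's arguments.
#'
#' @param path YAML file.
#' @return Object of class `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$seed)) args$seed <- y$seed
  if (!is.null(y$hidden)) args$hidden <- y$hidden
  if (!is.null(y$alpha_range)) args$alpha_range <- y$alpha_range
  if (!is.null(y$candidates)) args$candidates <- y$candidates
  if (!is.null(y$cohort)) {
    args$cohort <- if (is.character(y$cohort)) y$cohort else do.call(cohort_config, y$cohort)
  }
  if (!is.null(y$selection)) args$selection <- do.call(selection_config, y$selection)
  if (!is.null(y$split)) args$split <- do.call(split_spec, y$split)
  if (!is.null(y$ga)) args$ga <- if (isFALSE(y$ga)) NULL else do.call(ga_config, y$ga)
  if (!is.null(y$train)) args$train <- do.call(train_config, y$train)
  do.call(pipeline_config, args)
}

stage_log <- function(fmt, ...) message(sprintf(paste0("[bpgadose] ", fmt), ...))

#' Run the full pipeline
#'
#' Executes simulate/load, integrity filter, ANCOVA screen + mandatory
#' enrollment, split, scaling, hidden-size choice, GA weight search, BP
#' training and both validations. When `out_dir` is given, writes the cohort
#' CSV, selection and scaler JSON, model JSON, GA trajectory CSV, both
#' accuracy reports, the comparison record and a provenance manifest
#' embedding the master seed and a config hash. Identical configs produce
#' identical bundles.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Optional output directory (created if needed).
#' @return Invisibly, a list with the cohort, selected variables, scores,
#'   split sizes, chosen hidden size, fitted model, `internal`/`external`
#'   `accuracy_report`s, comparison record, and manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL) {
  t0 <- proc.time()[["elapsed"]]
  times <- list()
  tick <- function(stage, since) {
    now <- proc.time()[["elapsed"]]
    times[[stage]] <<- round(now - since, 3)
    now
  }
  seeds <- lapply(c(simulate = "simulate", select = "select", split = "split",
                    hidden = "hidden", ga = "ga"),
                  derive_seed, master = config$seed)

  # -- cohort -----------------------------------------------------------
  t <- t0
  if (is.character(config$cohort)) {
    cohort <- read_cohort(config$cohort)
    stage_log("loaded cohort from %s: %d rows", config$cohort, nrow(cohort))
  } else {
    cc <- config$cohort
    cc$seed <- seeds$simulate
    cohort <- generate_cohort(cc)
    stage_log("simulated cohort: %d rows, %d centres", nrow(cohort),
              length(unique(cohort$center_id)))
  }
  t <- tick("simulate", t)

  # -- variable selection ----------------------------------------------
  filt <- filter_integrity(cohort[, c(config$candidates, config$selection$mandatory,
                                      "dose_actual")],
                           config$selection$integrity_threshold)
  cand <- intersect(config$candidates, names(filt$table))
  scores <- ancova_partial_eta2(filt$table, "dose_actual", cand)
  selected <- select_variables(scores, config$selection)
  stage_log("selected %d variables: %s", length(selected), paste(selected, collapse = ", "))
  t <- tick("select", t)

  # -- split ------------------------------------------------------------
  sp <- config$split
  sp$seed <- seeds$split
  groups <- split_dataset(cohort, sp)
  stage_log("split: train %d / internal %d / external %d",
            nrow(groups$train), nrow(groups$internal), nrow(groups$external))
  t <- tick("split", t)

  # complete-case within the modelling columns
  used_cols <- c(selected, "dose_actual")
  cc_rows <- function(d) d[stats::complete.cases(d[, used_cols]), , drop = FALSE]
  groups <- lapply(groups, cc_rows)

  scaler <- fit_minmax(groups$train, used_cols)
  x_train <- apply_minmax(scaler, groups$train, selected)
  y_train <- as.vector(apply_minmax(scaler, groups$train, "dose_actual"))
  invert_dose <- function(v) invert_minmax(scaler, v, "dose_actual")

  # -- hidden size ------------------------------------------------------
  if (identical(config$hidden, "search")) {
    hs <- hidden_size_search(x_train, y_train, config$alpha_range,
                             seed = seeds$hidden, config = config$train,
                             invert = invert_dose)
    h <- hs$h
    stage_log("hidden-size search chose h = %d (candidate MAEs %s)",
              h, paste(sprintf("%d:%.3f", hs$table$h, hs$table$mae), collapse = " "))
  } else {
    h <- as.integer(config$hidden)
    hs <- NULL
    stage_log("fixed hidden size h = %d", h)
  }
  t <- tick("hidden", t)

  # -- GA + BP ----------------------------------------------------------
  ga <- config$ga
  if (!is.null(ga)) ga$seed <- seeds$ga
  model <- fit_bpga(x_train, y_train, h, ga = ga, train = config$train,
                    init_seed = seeds$ga)
  if (!is.null(model$ga)) {
    stage_log("GA best fitness %.4f; BP stopped after %d epochs (%s)",
              model$ga$best_fitness, model$bp$epochs, model$bp$stop_reason)
  } else {
    stage_log("BP (random init) stopped after %d epochs (%s)",
              model$bp$epochs, model$bp$stop_reason)
  }
  t <- tick("train", t)

  # -- validation -------------------------------------------------------
  validate <- function(g) {
    if (nrow(g) == 0) return(NULL)
    preds <- invert_dose(forward(model$params, apply_minmax(scaler, g, selected)))
    accuracy_report(preds, g$dose_actual)
  }
  internal <- validate(groups$internal)
  external <- validate(groups$external)
  if (is.null(external)) {
    warning("run_pipeline: external group is empty; no external report")
  }
  comparison <- if (!is.null(internal) && !is.null(external)) {
    compare_groups(internal, external)
  } else NULL
  if (!is.null(internal)) {
    stage_log("internal: MAE %.3f RMSE %.3f ideal %.1f%%",
              internal$mae, internal$rmse, internal$percentages[["ideal"]])
  }
  if (!is.null(external)) {
    stage_log("external: MAE %.3f RMSE %.3f ideal %.1f%%",
              external$mae, external$rmse, external$percentages[["ideal"]])
  }
  t <- tick("evaluate", t)

  stage_log("stage wall times (s): %s",
            paste(sprintf("%s %.2f", names(times), unlist(times)), collapse = ", "))

  # wall times are logged, not written, so identical configs give
  # byte-identical manifests
  config_json <- jsonlite::toJSON(rapply(unclass(config), unclass, how = "replace"),
                                  auto_unbox = TRUE, digits = NA, force = TRUE)
  manifest <- list(master_seed = config$seed,
                   config_hash = fnv1a_hash(as.character(config_json)),
                   stage_seeds = seeds,
                   chosen_hidden = h,
                   ga_best_fitness = model$ga$best_fitness,
                   n = list(cohort = nrow(cohort), train = nrow(groups$train),
                            internal = nrow(groups$internal),
                            external = nrow(groups$external)),
                   mae = list(internal = internal$mae,
                              external = if (!is.null(external)) external$mae))

  result <- list(cohort = cohort, scores = scores, selected = selected,
                 groups = groups, scaler = scaler, hidden_search = hs, h = h,
                 model = model, internal = internal, external = external,
                 comparison = comparison, manifest = manifest)

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_cohort(cohort, file.path(out_dir, "cohort.csv"))
    jsonlite::write_json(list(scores = scores, selected = selected,
                              thresholds = list(eta2 = config$selection$eta2_threshold,
                                                alpha = config$selection$alpha),
                              master_seed = config$seed,
                              config_hash = manifest$config_hash),
                         file.path(out_dir, "selection.json"),
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
    write_scaler(scaler, file.path(out_dir, "scaler.json"))
    write_model(model, file.path(out_dir, "model.json"))
    if (!is.null(model$ga)) {
      utils::write.csv(model$ga$trajectory, file.path(out_dir, "ga_trajectory.csv"),
                       row.names = FALSE)
    }
    write_report <- function(rep, file) {
      if (is.null(rep)) return()
      jsonlite::write_json(list(n = rep$n, mae = rep$mae, rmse = rep$rmse,
                                counts = as.list(rep$counts),
                                percentages = as.list(rep$percentages),
                                subgroups = lapply(rep$subgroups, function(s) {
                                  list(n = s$n, counts = as.list(s$counts),
                                       percentages = as.list(s$percentages))
                                }),
                                master_seed = config$seed,
                                config_hash = manifest$config_hash),
                           file.path(out_dir, file), auto_unbox = TRUE, digits = NA)
    }
    write_report(internal, "report_internal.json")
    write_report(external, "report_external.json")
    if (!is.null(comparison)) {
      jsonlite::write_json(c(comparison, list(master_seed = config$seed,
                                              config_hash = manifest$config_hash)),
                           file.path(out_dir, "comparison.json"),
                           auto_unbox = TRUE, digits = NA)
    }
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  invisible(result)
}
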