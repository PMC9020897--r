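#' Configure an end-to-end prediction run
#'
#' Collects every choice the pipeline makes, with defaults reproducing
#' the reference protocol where one is stated: top-12 feature selection,
#' the reference optimizer settings, Softsign candidate activation,
#' 80/20 stratified split.
#'
#' @param data A cohort data frame, a CSV path, or `NULL` to simulate.
#' @param n Cohort size when simulating (default 2000).
#' @param seed Master seed driving simulation, ranking, splitting and
#'   training.
#' @param dup_count,outliers Planted anomalies when simulating (see
#'   [cohort_spec()]).
#' @param lower_q,upper_q Height/weight trim quantiles (default 0.05 /
#'   0.95).
#' @param top_k Features kept after importance ranking (default 12).
#' @param n_trees Forest size for the ranking (default 100).
#' @param encoding `"per_feature_step"` or `"single_step"`.
#' @param hidden_dim LSTM hidden size (default 16).
#' @param variant `"softsign"` (default) or `"standard"`.
#' @param optimizer Optimizer name (default `"r-lookahead"`).
#' @param opt_cfg Optional optimizer config overrides.
#' @param epochs Training epochs (default 50).
#' @param batch_size Mini-batch size (default 64).
#' @param split_fraction Train fraction of the stratified split (default
#'   0.8).
#' @param threshold Decision threshold (default 0.5).
#' @param output_dir Directory for persisted artifacts (`NULL` = none).
#' @return A `run_config` list.
#' @export
run_config <- function(data = NULL, n = 2000, seed = 42,
                       dup_count = 0, outliers = list(),
                       lower_q = 0.05, upper_q = 0.95,
                       top_k = 12, n_trees = 100,
                       encoding = "per_feature_step",
                       hidden_dim = 16, variant = "softsign",
                       optimizer = "r-lookahead", opt_cfg = NULL,
                       epochs = 50, batch_size = 64,
                       split_fraction = 0.8, threshold = 0.5,
                       output_dir = NULL) {
  stopifnot(split_fraction > 0, split_fraction < 1)
  structure(as.list(environment()), class = "run_config")
}

#' Stratified train/test split
#'
#' Seeded split preserving the label ratio within one record per class:
#' each class is shuffled and `round(fraction * n_class)` records go to
#' the training set.
#'
#' @param table Data frame with the label column.
#' @param fraction Train fraction in (0, 1).
#' @param seed Integer seed.
#' @param label Label column name.
#' @return List of tibbles `train`, `test` (a disjoint partition).
#' @export
split_cohort <- function(table, fraction = 0.8, seed = 1L,
                         label = "cardio") {
  stopifnot(fraction > 0, fraction < 1)
  classes <- unique(table[[label]])
  if (length(classes) < 2) {
    stop("a class is absent; cannot stratify", call. = FALSE)
  }
  idx_train <- withr::with_seed(as.integer(seed), {
    unlist(lapply(classes, function(cl) {
      rows <- which(table[[label]] == cl)
      rows <- rows[sample.int(length(rows))]
      rows[seq_len(round(fraction * length(rows)))]
    }))
  })
  list(train = tibble::as_tibble(table[idx_train, , drop = FALSE]),
       test = tibble::as_tibble(table[-idx_train, , drop = FALSE]))
}

# Shared data preparation: simulate/load -> clean -> derive -> rank ->
# select -> normalise -> one-hot -> split. Returns everything training
# needs, so run_pipeline and compare_optimizers see identical inputs.
.prepare_run <- function(config) {
  stopifnot(inherits(config, "run_config"))
  if (is.null(config$data)) {
    spec <- cohort_spec(config$n, seed = config$seed,
                        dup_count = config$dup_count,
                        outliers = config$outliers)
    raw <- plant_anomalies(generate_cohort(spec), spec)
  } else if (is.character(config$data)) {
    raw <- read_cohort_csv(config$data)
  } else {
    raw <- tibble::as_tibble(config$data)
  }

  cleaned <- clean_cohort(raw, lower_q = config$lower_q,
                          upper_q = config$upper_q)
  report <- cleaning_report(cleaned)
  feats <- add_derived_features(cleaned)

  importance <- rank_features(feats, label = "cardio",
                              n_trees = config$n_trees,
                              seed = config$seed)
  selected <- select_top_k(importance, k = config$top_k)

  model_tbl <- normalize_features(feats)
  model_features <- selected
  if ("gender" %in% selected) {
    model_tbl <- encode_onehot_column(model_tbl, "gender")
    gcols <- grep("^gender_", names(model_tbl), value = TRUE)
    model_features <- unlist(lapply(selected, function(f) {
      if (f == "gender") gcols else f
    }))
  }

  halves <- split_cohort(model_tbl, fraction = config$split_fraction,
                         seed = config$seed)
  list(raw = raw, cleaned = cleaned, report = report,
       importance = importance, selected = selected,
       model_features = model_features, train = halves$train,
       test = halves$test)
}

#' Run the full prediction pipeline
#'
#' Executes the whole workflow in order — simulate (or load) a cohort,
#' deduplicate and filter, derive BMI/MAP/PP, rank features by forest Gini
#' importance, keep the top `k`, min-max normalise, encode records as
#' sequences, train the LSTM under the configured optimizer, and evaluate
#' on the held-out split. Fully reproducible from `(config, seed)`. When
#' `config$output_dir` is set, persists `cleaning_report.json`,
#' `importance.csv`, `checkpoint.json` and `metrics.json`.
#'
#' @param config A [run_config()].
#' @return A `cardio_run` object: cleaning report, importance ranking,
#'   selected features, the trained `cardio_lstm`, held-out `metrics`, and
#'   the config.
#' @export
run_pipeline <- function(config) {
  prep <- .run_stage("prepare", .prepare_run(config))
  model <- .run_stage("train", train_lstm(
    as.matrix(prep$train[prep$model_features]), prep$train$cardio,
    hidden_dim = config$hidden_dim, variant = config$variant,
    optimizer = config$optimizer, opt_cfg = config$opt_cfg,
    epochs = config$epochs, batch_size = config$batch_size,
    seed = config$seed, mode = config$encoding
  ))
  metrics <- .run_stage("evaluate", evaluate_model(
    model, prep$test, threshold = config$threshold
  ))

  run <- structure(list(
    config = config,
    rows = list(raw = nrow(prep$raw), cleaned = nrow(prep$cleaned),
                train = nrow(prep$train), test = nrow(prep$test)),
    cleaning_report = prep$report,
    importance = prep$importance,
    selected = prep$selected,
    model = model,
    metrics = metrics
  ), class = "cardio_run")

  if (!is.null(config$output_dir)) {
    dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
    p <- function(f) file.path(config$output_dir, f)
    jsonlite::write_json(
      list(removed_per_rule = as.list(stats::setNames(
        prep$report$removed, prep$report$rule)),
        rows_before = attr(prep$report, "rows_before"),
        rows_after = attr(prep$report, "rows_after")),
      p("cleaning_report.json"), auto_unbox = TRUE)
    readr::write_csv(prep$importance[c("feature", "importance")],
                     p("importance.csv"))
    save_checkpoint(model, p("checkpoint.json"))
    jsonlite::write_json(as.list(metrics), p("metrics.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  run
}

.run_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e) {
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  })
}

#' @export
print.cardio_run <- function(x, ...) {
  cat("Cardio risk prediction run\n")
  cat("  rows: raw ", x$rows$raw, " -> cleaned ", x$rows$cleaned,
      " (train ", x$rows$train, " / test ", x$rows$test, ")\n", sep = "")
  cat("  selected features: ", paste(x$selected, collapse = ", "),
      "\n", sep = "")
  cat("  optimizer ", x$model$optimizer, ", variant ", x$model$variant,
      "\n  held-out metrics:\n", sep = "")
  print(as.data.frame(round(x$metrics, 4)))
  invisible(x)
}

#' Compare optimizers on an identical model and data
#'
#' Trains one model per optimizer from the same seed, data split and
#' initial weights, recording held-out accuracy and loss at the checkpoint
#' step counts (default 500/1000/1500/2000). Per-optimizer failures are
#' recorded and the comparison continues.
#'
#' @param config A [run_config()].
#' @param optimizers Character vector of at least two optimizer names.
#' @param checkpoint_steps Steps at which to evaluate.
#' @return An `optimizer_comparison` tibble: `optimizer`, `step`,
#'   `accuracy`, `loss`, `error`.
#' @seealso [comparison_wide()] for the table-shaped layout.
#' @export
compare_optimizers <- function(config, optimizers,
                               checkpoint_steps = c(500, 1000, 1500,
                                                    2000)) {
  if (length(optimizers) < 2) {
    stop("need at least two optimizers to compare", call. = FALSE)
  }
  prep <- .prepare_run(config)
  xtr <- as.matrix(prep$train[prep$model_features])
  xte <- as.matrix(prep$test[prep$model_features])
  rows <- lapply(optimizers, function(opt_name) {
    res <- tryCatch({
      model <- train_lstm(
        xtr, prep$train$cardio, hidden_dim = config$hidden_dim,
        variant = config$variant, optimizer = opt_name,
        opt_cfg = config$opt_cfg, max_steps = max(checkpoint_steps),
        batch_size = config$batch_size, seed = config$seed,
        mode = config$encoding, checkpoint_steps = checkpoint_steps,
        eval_x = xte, eval_y = prep$test$cardio
      )
      dplyr::mutate(model$checkpoints, optimizer = opt_name,
                    error = NA_character_)
    }, error = function(e) {
      tibble::tibble(step = checkpoint_steps, accuracy = NA_real_,
                     loss = NA_real_, optimizer = opt_name,
                     error = conditionMessage(e))
    })
    res
  })
  out <- dplyr::relocate(dplyr::bind_rows(rows), "optimizer")
  class(out) <- c("optimizer_comparison", class(out))
  out
}

#' Reshape an optimizer comparison into the wide table layout
#'
#' One row per optimizer, one column per checkpoint step, for a chosen
#' metric — the layout used to report accuracy/loss against iteration
#' count.
#'
#' @param comparison An [compare_optimizers()] tibble.
#' @param metric `"accuracy"` or `"loss"`.
#' @return A wide tibble `optimizer`, `<step1>`, `<step2>`, ...
#' @export
comparison_wide <- function(comparison, metric = c("accuracy", "loss")) {
  metric <- match.arg(metric)
  tidyr::pivot_wider(
    comparison[c("optimizer", "step", metric)],
    names_from = "step", values_from = dplyr::all_of(metric)
  )
}
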