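# End-to-end experiment orchestration: clean -> stratified 70/30 split ->
# min-max normalization -> (optional GA feature selection + LDA mapping) ->
# decision tree -> diagnostic metrics on the held-out partition.

#' Experiment configuration
#'
#' Describes one run of the classification pipeline. `mode = "raw_features"`
#' trains the tree on all normalized features; `mode = "ga_lda"` first runs
#' the genetic-algorithm wrapper on the training partition, restricts both
#' partitions to the selected features, and maps them to one dimension with
#' LDA before the tree. A single master `seed` derives independent streams
#' for the split and the GA, so toggling one stage leaves the other's
#' randomness unchanged.
#'
#' @param mode `"ga_lda"` (default) or `"raw_features"`.
#' @param split_fraction Outer training proportion (default 0.7).
#' @param shrinkage LDA diagonal shrinkage.
#' @param ga A [ga_config()]; its seed is overridden by the derived stream.
#' @param tree A [tree_config()].
#' @param paper_mode If `TRUE`, min-max normalization is fitted on all rows
#'   before splitting (the literal historical order of operations) instead
#'   of the leakage-safe training-only fit, and the GA uses a single fixed
#'   inner split.
#' @param seed Master seed.
#' @return An `experiment_config` list.
#' @export
experiment_config <- function(mode = c("ga_lda", "raw_features"),
                              split_fraction = 0.7, shrinkage = 1e-3,
                              ga = ga_config(), tree = tree_config(),
                              paper_mode = FALSE, seed = 1L) {
  mode <- match.arg(mode)
  structure(list(mode = mode, split_fraction = split_fraction,
                 shrinkage = shrinkage, ga = ga, tree = tree,
                 paper_mode = paper_mode, seed = as.integer(seed)),
            class = "experiment_config")
}

#' Run one classification experiment
#'
#' Executes the full pipeline on a feature table and evaluates on the
#' held-out 30% partition: cleaning, stratified splitting, min-max
#' normalization fitted on the training rows (unless `paper_mode`), optional
#' GA feature selection and LDA mapping (both fitted on training only; the
#' selected features and fitted transforms are then applied unchanged to the
#' test rows), decision-tree fitting, and diagnostic-metric evaluation.
#'
#' @param table A feature table.
#' @param config An [experiment_config()].
#' @return A `run_report` with feature counts before/after selection, the
#'   selected feature names, held-out metrics, and the frozen artifacts
#'   (normalization, chromosome, LDA map, tree) needed by
#'   [validate_on_unseen()].
#' @export
run_experiment <- function(table, config = experiment_config()) {
  assert_feature_table(table)
  table <- suppressMessages(clean_features(table))
  n_before <- length(feature_names(table))

  split <- split_samples(table, config$split_fraction,
                         seed = derive_seed(config$seed, "outer-split"))
  train <- table[split$train, ]
  test <- table[split$test, ]

  norm <- if (config$paper_mode) fit_minmax(table) else fit_minmax(train)
  train_n <- apply_minmax(train, norm)
  test_n <- apply_minmax(test, norm)

  ga_fit <- NULL
  lda_fit <- NULL
  if (config$mode == "ga_lda") {
    ga_cfg <- config$ga
    ga_cfg$seed <- derive_seed(config$seed, "ga-stream")
    ga_cfg$paper_mode <- ga_cfg$paper_mode || config$paper_mode
    ga_fit <- run_ga(train_n, ga_cfg, config$tree)
    keep <- c("sample_id", "label", ga_fit$selected_features)
    train_n <- set_value_kind(train_n[keep], "normalized")
    test_n <- set_value_kind(test_n[keep], "normalized")
    lda_fit <- fit_lda(train_n, config$shrinkage)
    train_n <- lda_transform(train_n, lda_fit)
    test_n <- lda_transform(test_n, lda_fit)
  }

  tree_fit <- fit_c45(train_n, config$tree)
  pred <- predict(tree_fit, test_n)
  metrics <- diagnostic_metrics(confusion(test_n$label, pred))

  n_after <- length(feature_names(train_n))
  selected <- if (is.null(ga_fit)) feature_names(table) else ga_fit$selected_features
  structure(list(
    mode = config$mode,
    n_features_before = n_before,
    n_features_after = if (is.null(ga_fit)) n_before else length(selected),
    feature_reduction_percent =
      if (is.null(ga_fit)) 0 else 100 * (1 - length(selected) / n_before),
    selected_features = selected,
    metrics = metrics,
    split = split,
    artifacts = list(normalization = norm, ga = ga_fit, lda = lda_fit,
                     tree = tree_fit),
    config = config
  ), class = "run_report")
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> mode %s: %d -> %d features (%.1f%% reduction)\n",
              x$mode, x$n_features_before, x$n_features_after,
              x$feature_reduction_percent))
  print(render_report(x))
  invisible(x)
}

#' Evaluate frozen pipeline artifacts on new data
#'
#' Applies the stored normalization, feature selection, LDA mapping and tree
#' to a new feature table without any refitting, and reports diagnostic
#' metrics. The new table must carry the training schema.
#'
#' @param report A `run_report` from [run_experiment()].
#' @param new_table A feature table with the same feature columns.
#' @return A `metrics_report`.
#' @export
validate_on_unseen <- function(report, new_table) {
  stopifnot(inherits(report, "run_report"))
  assert_feature_table(new_table)
  if (nrow(new_table) == 0) abort("New table is empty.")
  missing <- setdiff(report$artifacts$normalization$feature, feature_names(new_table))
  if (length(missing) > 0) {
    abort(paste0("Schema drift: new table lacks feature(s) ",
                 paste(head(missing, 5), collapse = ", ")))
  }
  tbl <- new_table[c("sample_id", "label", report$artifacts$normalization$feature)]
  tbl <- apply_minmax(tbl, report$artifacts$normalization)
  if (report$mode == "ga_lda") {
    tbl <- set_value_kind(tbl[c("sample_id", "label", report$selected_features)],
                          "normalized")
    tbl <- lda_transform(tbl, report$artifacts$lda)
  }
  pred <- predict(report$artifacts$tree, tbl)
  diagnostic_metrics(confusion(tbl$label, pred))
}

#' Render a run report as a result-table row
#'
#' One row in the layout of the study's result tables: a status column
#' (feature count and mode), then sensitivity, specificity, LR+, LR-, PPV,
#' NPV, accuracy and the two error counts, with percentages as integers and
#' likelihood ratios to two decimals; `Inf` prints literally.
#'
#' @param report A `run_report`.
#' @return A one-row character tibble.
#' @export
render_report <- function(report) {
  status <- if (report$mode == "ga_lda") {
    sprintf("%d (GA + LDA)", report$n_features_after)
  } else {
    sprintf("%d Raw Features", report$n_features_before)
  }
  dplyr::bind_cols(tibble(status = status), format_metrics(report$metrics))
}

#' Parse a rendered result row back into numbers
#'
#' Inverse of [render_report()] at rendered precision: `"Inf"` becomes `Inf`
#' and numeric strings become numbers.
#'
#' @param rendered A one-row tibble as produced by [render_report()].
#' @return A tibble with numeric metric columns plus `status`.
#' @export
parse_report <- function(rendered) {
  num <- function(s) ifelse(s == "Inf", Inf, as.numeric(s))
  out <- rendered
  for (col in setdiff(names(out), "status")) out[[col]] <- num(out[[col]])
  out
}

#' @rdname run_experiment
#' @param x A `run_report`.
#' @param ... Unused.
#' @export
tidy.run_report <- function(x, ...) {
  dplyr::bind_cols(tibble(mode = x$mode,
                          n_features_before = x$n_features_before,
                          n_features_after = x$n_features_after,
                          feature_reduction_percent = x$feature_reduction_percent),
                   as_tibble(x$metrics))
}

#' @rdname run_experiment
#' @export
glance.run_report <- function(x, ...) {
  tibble(mode = x$mode,
         accuracy = x$metrics$accuracy,
         sensitivity = x$metrics$sensitivity,
         specificity = x$metrics$specificity,
         n_features_after = x$n_features_after,
         feature_reduction_percent = x$feature_reduction_percent)
}

#' Write or read a feature table as delimited text
#'
#' Comma-separated with header `sample_id,label,<feature>...`; feature names
#' follow the `<electrode>_<band>_<condition>_<reference>` convention.
#'
#' @param table A feature table.
#' @param path File path.
#' @return `write_feature_table()` returns `table` invisibly;
#'   `read_feature_table()` returns the feature table.
#' @export
write_feature_table <- function(table, path) {
  assert_feature_table(table)
  readr::write_csv(table, path)
  invisible(table)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE)
  out$label <- as_label_factor(out$label)
  assert_feature_table(out)
  set_value_kind(out, "absolute_power")
}
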