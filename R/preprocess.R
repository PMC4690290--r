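# Cleaning, min-max normalization and stratified train/test partitioning.

#' Drop samples with missing feature values
#'
#' Rows containing any missing feature value are removed and the count is
#' reported. A column that is missing for every sample is an error (dropping
#' rows cannot repair it) and is named in the message.
#'
#' @param table A feature table.
#' @return The cleaned feature table.
#' @export
clean_features <- function(table) {
  assert_feature_table(table)
  feats <- feature_names(table)
  all_na <- feats[vapply(table[feats], function(x) all(is.na(x)), TRUE)]
  if (length(all_na) > 0) {
    abort(paste0("Feature column(s) entirely missing: ",
                 paste(all_na, collapse = ", ")))
  }
  keep <- !Reduce(`|`, lapply(table[feats], is.na))
  if (sum(keep) == 0) abort("All rows contain missing values.")
  n_drop <- sum(!keep)
  if (n_drop > 0) inform(sprintf("Dropped %d row(s) with missing values.", n_drop))
  out <- table[keep, ]
  set_value_kind(out, value_kind(table))
}

#' Fit min-max normalization parameters
#'
#' Records the per-feature minimum and maximum of the supplied (training)
#' rows, for the linear map
#' \deqn{v' = \frac{v - min_A}{max_A - min_A}(new\_max_A - new\_min_A) + new\_min_A}
#' A constant feature (max equal to min) is flagged as degenerate and later
#' mapped to `new_min`.
#'
#' @param train A feature table with at least two rows.
#' @param new_range Target range, default `c(0, 1)`.
#' @return A `minmax_params` object (tibble of `feature`, `min`, `max`,
#'   `degenerate`, with the target range as attributes).
#' @export
fit_minmax <- function(train, new_range = c(0, 1)) {
  assert_feature_table(train)
  if (nrow(train) < 2) abort("Need at least 2 rows to fit normalization.")
  if (new_range[2] <= new_range[1]) abort("`new_range` must be increasing.")
  m <- ft_matrix(train)
  params <- tibble(
    feature = colnames(m),
    min = unname(apply(m, 2, min)),
    max = unname(apply(m, 2, max))
  )
  params$degenerate <- params$max == params$min
  if (any(params$degenerate)) {
    warn(paste0("Constant (degenerate) feature(s): ",
                paste(params$feature[params$degenerate], collapse = ", ")))
  }
  structure(params, class = c("minmax_params", class(params)),
            new_min = new_range[1], new_max = new_range[2])
}

#' Apply a fitted min-max normalization
#'
#' Training rows map exactly into `[new_min, new_max]`; rows outside the
#' training range (e.g. test samples) map outside it and are deliberately not
#' clipped, preserving monotonicity for threshold-based classifiers.
#' Degenerate features map to `new_min`.
#'
#' @param table A feature table whose features match `params`.
#' @param params A `minmax_params` from [fit_minmax()].
#' @return The normalized feature table (`value_kind = "normalized"`).
#' @export
apply_minmax <- function(table, params) {
  assert_feature_table(table)
  stopifnot(inherits(params, "minmax_params"))
  feats <- feature_names(table)
  unknown <- setdiff(feats, params$feature)
  if (length(unknown) > 0) {
    abort(paste0("Feature(s) not covered by normalization parameters: ",
                 paste(unknown, collapse = ", ")))
  }
  new_min <- attr(params, "new_min")
  new_max <- attr(params, "new_max")
  out <- table
  idx <- match(feats, params$feature)
  for (j in seq_along(feats)) {
    p <- params[idx[j], ]
    v <- table[[feats[j]]]
    out[[feats[j]]] <- if (p$degenerate) {
      rep(new_min, length(v))
    } else {
      (v - p$min) / (p$max - p$min) * (new_max - new_min) + new_min
    }
  }
  set_value_kind(out, "normalized")
}

#' Invert a min-max normalization
#'
#' Analytic inverse of [apply_minmax()] for non-degenerate features.
#'
#' @inheritParams apply_minmax
#' @return The de-normalized feature table.
#' @export
invert_minmax <- function(table, params) {
  stopifnot(inherits(params, "minmax_params"))
  new_min <- attr(params, "new_min")
  new_max <- attr(params, "new_max")
  out <- table
  for (j in feature_names(table)) {
    p <- params[match(j, params$feature), ]
    if (!p$degenerate) {
      out[[j]] <- (table[[j]] - new_min) / (new_max - new_min) * (p$max - p$min) + p$min
    }
  }
  set_value_kind(out, "absolute_power")
}

#' Stratified train/test split
#'
#' Draws `floor(fraction * n_class)` training samples independently within
#' each class, so the split preserves the MDD/HV imbalance. With the study's
#' 53 MDD / 43 HV and a 0.7 fraction this gives 37 + 30 = 67 training and 29
#' test samples. Deterministic under `seed`.
#'
#' @param table A feature table with at least 2 samples per class.
#' @param fraction Training proportion in (0, 1), default 0.7.
#' @param seed Integer seed.
#' @return A `split_indices` list with integer vectors `train` and `test`,
#'   plus `fraction` and `seed`.
#' @export
split_samples <- function(table, fraction = 0.7, seed = 1L) {
  assert_feature_table(table)
  if (fraction <= 0 || fraction >= 1) abort("`fraction` must be in (0, 1).")
  lab <- as_label_factor(table$label)
  if (any(table(lab) < 2)) abort("Need at least 2 samples per class to split.")
  train <- integer(0)
  withr::with_seed(seed, {
    for (cl in levels(lab)) {
      ix <- which(lab == cl)
      n_tr <- floor(fraction * length(ix))
      train <- c(train, sort(sample(ix, n_tr)))
    }
  })
  train <- sort(train)
  structure(list(train = train, test = setdiff(seq_len(nrow(table)), train),
                 fraction = fraction, seed = as.integer(seed)),
            class = "split_indices")
}
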