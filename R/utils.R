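# Shared internal helpers: feature-table accessors, class conventions,
# seed derivation for the master-seed hierarchy.

# Positive class first: MDD is "depressed", HV "healthy volunteer".
.classes <- c("MDD", "HV")

#' Feature column names of a feature table
#'
#' A feature table is a tibble with a `sample_id` column, a `label` column
#' (factor with levels `MDD`, `HV`) and one numeric column per band-power
#' feature. Everything except `sample_id` and `label` counts as a feature.
#'
#' @param table A feature table.
#' @return Character vector of feature column names.
#' @export
feature_names <- function(table) {
  setdiff(names(table), c("sample_id", "label"))
}

# Numeric matrix view of the feature columns (rows = samples).
ft_matrix <- function(table) {
  m <- as.matrix(table[feature_names(table)])
  storage.mode(m) <- "double"
  m
}

assert_feature_table <- function(table, call = rlang::caller_env()) {
  if (!is.data.frame(table) || !all(c("sample_id", "label") %in% names(table))) {
    abort("`table` must be a feature table with `sample_id` and `label` columns.",
          call = call)
  }
  bad <- setdiff(unique(as.character(table$label)), .classes)
  if (length(bad) > 0) {
    abort(paste0("Unknown class label(s): ", paste(bad, collapse = ", "),
                 ". Labels must be 'MDD' or 'HV'."), call = call)
  }
  invisible(table)
}

as_label_factor <- function(x) factor(as.character(x), levels = .classes)

value_kind <- function(table) attr(table, "value_kind") %||% "absolute_power"

set_value_kind <- function(table, kind) {
  attr(table, "value_kind") <- kind
  table
}

# Derive an independent sub-seed from a master seed and a stage name, so that
# toggling one randomized stage does not shift another's stream. Kept inside
# the 32-bit signed integer range.
derive_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  s <- (as.numeric(seed) * 48271 + h * 7919) %% 2147483629
  as.integer(s) + 1L
}

# Small checksum of a numeric vector/list of fitted parameters, used for
# leakage assertions in tests.
param_checksum <- function(x) {
  v <- unlist(x, use.names = FALSE)
  v <- v[is.finite(as.numeric(v))]
  sum(as.numeric(v) * seq_along(v))
}
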