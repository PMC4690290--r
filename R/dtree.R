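# C4.5-style decision tree for continuous features and two classes:
# gain-ratio criterion with the average-gain guard, midpoint thresholds,
# optional pessimistic (confidence-bound) pruning.

#' Shannon entropy of class counts
#'
#' Entropy in bits, with the convention `0 * log2(0) = 0`.
#'
#' @param counts Non-negative class counts, not all zero.
#' @return Entropy in bits.
#' @examples
#' entropy_bits(c(5, 5))   # 1
#' entropy_bits(c(9, 5))   # 0.9403
#' @export
entropy_bits <- function(counts) {
  if (any(counts < 0) || sum(counts) == 0) abort("Counts must be >= 0, not all zero.")
  p <- counts[counts > 0] / sum(counts)
  -sum(p * log2(p))
}

#' Decision-tree hyperparameters
#'
#' @param min_leaf Minimum samples per leaf (default 2).
#' @param max_depth Maximum tree depth, `Inf` for unlimited.
#' @param pruning `"none"` (default) or `"pessimistic"` subtree replacement
#'   using an upper binomial confidence bound on the leaf error rate.
#' @param cf Confidence factor for pessimistic pruning (default 0.25).
#' @return A `tree_config` list.
#' @export
tree_config <- function(min_leaf = 2, max_depth = Inf,
                        pruning = c("none", "pessimistic"), cf = 0.25) {
  pruning <- match.arg(pruning)
  if (min_leaf < 1) abort("`min_leaf` must be >= 1.")
  structure(list(min_leaf = min_leaf, max_depth = max_depth,
                 pruning = pruning, cf = cf), class = "tree_config")
}

# Candidate splits for one feature: midpoints between consecutive distinct
# values whose class composition differs. Returns tibble(threshold, gain,
# gain_ratio) honoring min_leaf.
feature_candidates <- function(x, y01, min_leaf) {
  ord <- order(x)
  xs <- x[ord]
  ys <- y01[ord]
  n <- length(xs)
  grp_end <- which(c(xs[-n] < xs[-1], TRUE))      # last index of each distinct value
  if (length(grp_end) < 2) return(NULL)
  cum1 <- cumsum(ys)[grp_end]                      # class-1 count up to group
  cumn <- grp_end
  g_mdd <- diff(c(0, cum1))                        # per-group class counts
  g_n <- diff(c(0, cumn))
  g_hv <- g_n - g_mdd
  k <- length(grp_end)
  # boundary between group i and i+1 is a candidate unless both groups are
  # pure and of the same class
  same_pure <- (g_hv[-k] == 0 & g_hv[-1] == 0) | (g_mdd[-k] == 0 & g_mdd[-1] == 0)
  nl <- cumn[-k]
  ok <- !same_pure & nl >= min_leaf & (n - nl) >= min_leaf
  if (!any(ok)) return(NULL)
  n1 <- sum(ys)
  h_parent <- entropy_bits(c(n1, n - n1))
  l1 <- cum1[-k][ok]
  ln <- nl[ok]
  r1 <- n1 - l1
  rn <- n - ln
  h2 <- function(a, nn) {
    h <- numeric(length(a))
    for (i in seq_along(a)) h[i] <- entropy_bits(c(a[i], nn[i] - a[i]))
    h
  }
  gain <- h_parent - (ln / n) * h2(l1, ln) - (rn / n) * h2(r1, rn)
  split_info <- -(ln / n) * log2(ln / n) - (rn / n) * log2(rn / n)
  uniq_vals <- xs[grp_end]
  thr <- (uniq_vals[-k][ok] + uniq_vals[-1][ok]) / 2
  tibble(threshold = thr, gain = gain, gain_ratio = gain / split_info)
}

#' Best gain-ratio split of a node
#'
#' Enumerates, for every feature, the midpoints between consecutive distinct
#' sorted values where the class composition changes, then applies the C4.5
#' selection rule: among candidates whose information gain is at least the
#' mean gain of all candidates, choose the one with the highest gain ratio.
#' Ties break to the lowest feature index, then the lowest threshold.
#'
#' @param x Numeric matrix (samples x features).
#' @param labels Class labels (`MDD`/`HV`).
#' @param min_leaf Minimum samples on each side of the split.
#' @return A one-row tibble `feature_index`, `threshold`, `gain`,
#'   `gain_ratio`, or `NULL` when no admissible split exists.
#' @export
best_split <- function(x, labels, min_leaf = 2) {
  y01 <- as.integer(as_label_factor(labels) == "MDD")
  if (length(unique(y01)) < 2 || nrow(x) < 2 * min_leaf) return(NULL)
  cand <- purrr::map(seq_len(ncol(x)), function(j) {
    cc <- feature_candidates(x[, j], y01, min_leaf)
    if (is.null(cc)) return(NULL)
    cc$feature_index <- j
    cc
  })
  cand <- dplyr::bind_rows(cand)
  if (nrow(cand) == 0) return(NULL)
  cand <- cand[cand$gain > 1e-12, ]
  if (nrow(cand) == 0) return(NULL)
  adm <- cand[cand$gain >= mean(cand$gain) - 1e-12, ]
  adm <- adm[order(-adm$gain_ratio, adm$feature_index, adm$threshold), ]
  adm[1, c("feature_index", "threshold", "gain", "gain_ratio")]
}

node_counts <- function(labels) {
  c(MDD = sum(labels == "MDD"), HV = sum(labels == "HV"))
}

grow_tree <- function(x, labels, cfg, depth) {
  counts <- node_counts(labels)
  leaf <- function() {
    # majority label; tie goes to the first-listed class (MDD)
    list(type = "leaf", label = .classes[which.max(counts)],
         counts = counts, n = sum(counts), depth = depth)
  }
  if (min(counts) == 0 || depth >= cfg$max_depth || sum(counts) < 2 * cfg$min_leaf) {
    return(leaf())
  }
  sp <- best_split(x, labels, cfg$min_leaf)
  if (is.null(sp)) return(leaf())
  go_left <- x[, sp$feature_index] <= sp$threshold
  list(type = "split",
       feature_index = sp$feature_index,
       threshold = sp$threshold,
       gain = sp$gain, gain_ratio = sp$gain_ratio,
       counts = counts, n = sum(counts), depth = depth,
       left = grow_tree(x[go_left, , drop = FALSE], labels[go_left], cfg, depth + 1),
       right = grow_tree(x[!go_left, , drop = FALSE], labels[!go_left], cfg, depth + 1))
}

# Upper confidence bound on the true error rate of a leaf observing E errors
# in N samples (Clopper-Pearson style upper limit at confidence factor cf).
pessimistic_errors <- function(E, N, cf) {
  if (N == 0) return(0)
  ub <- if (E >= N) 1 else qbeta(1 - cf, E + 1, N - E)
  N * ub
}

prune_node <- function(node, cf) {
  if (node$type == "leaf") return(node)
  node$left <- prune_node(node$left, cf)
  node$right <- prune_node(node$right, cf)
  subtree_est <- function(nd) {
    if (nd$type == "leaf") {
      pessimistic_errors(nd$n - max(nd$counts), nd$n, cf)
    } else {
      subtree_est(nd$left) + subtree_est(nd$right)
    }
  }
  as_leaf_est <- pessimistic_errors(node$n - max(node$counts), node$n, cf)
  if (as_leaf_est <= subtree_est(node)) {
    return(list(type = "leaf", label = .classes[which.max(node$counts)],
                counts = node$counts, n = node$n, depth = node$depth))
  }
  node
}

#' Fit a C4.5-style decision tree
#'
#' Recursively splits on the feature/threshold chosen by [best_split()] until
#' nodes are pure, fall below `2 * min_leaf` samples, or reach `max_depth`.
#' Leaves predict their majority class (ties go to MDD, the first-listed
#' class). Optional pessimistic pruning replaces a subtree by a leaf when the
#' leaf's upper-bound error estimate does not exceed the subtree's.
#'
#' @param train A feature table.
#' @param config A [tree_config()].
#' @return A `c45_tree` object.
#' @examples
#' fx <- worked_fixtures()
#' tree <- fit_c45(fx$toy_table)
#' predict(tree, fx$toy_table)
#' @export
fit_c45 <- function(train, config = tree_config()) {
  assert_feature_table(train)
  if (nrow(train) < 1) abort("Need at least one training sample.")
  x <- ft_matrix(train)
  labels <- as_label_factor(train$label)
  root <- grow_tree(x, labels, config, depth = 0)
  if (config$pruning == "pessimistic") root <- prune_node(root, config$cf)
  structure(list(root = root, features = colnames(x), config = config),
            class = "c45_tree")
}

route <- function(node, row) {
  while (node$type != "leaf") {
    node <- if (row[node$feature_index] <= node$threshold) node$left else node$right
  }
  node$label
}

# matrix-level prediction used inside the GA fitness loop
predict_c45_matrix <- function(tree, m) {
  as_label_factor(vapply(seq_len(nrow(m)), function(i) route(tree$root, m[i, ]), ""))
}

#' Predict classes with a fitted tree
#'
#' Rows are routed deterministically: a value equal to the split threshold
#' goes left (the `<=` branch).
#'
#' @param object A `c45_tree`.
#' @param newdata A feature table containing the tree's features.
#' @param ... Unused.
#' @return Factor of predicted labels.
#' @export
predict.c45_tree <- function(object, newdata, ...) {
  missing <- setdiff(object$features, names(newdata))
  if (length(missing) > 0) {
    abort(paste0("Missing feature(s): ", paste(missing, collapse = ", ")))
  }
  m <- as.matrix(newdata[object$features])
  predict_c45_matrix(object, m)
}

walk_nodes <- function(node, id = 1L) {
  nd <- node  # the tibble column named `node` must not shadow the argument
  is_split <- nd$type == "split"
  row <- tibble(
    node = id, depth = nd$depth, type = nd$type,
    feature_index = if (is_split) nd$feature_index else NA_integer_,
    threshold = if (is_split) nd$threshold else NA_real_,
    gain_ratio = if (is_split) nd$gain_ratio else NA_real_,
    n = nd$n, n_mdd = nd$counts[["MDD"]], n_hv = nd$counts[["HV"]],
    label = if (is_split) NA_character_ else nd$label
  )
  if (node$type == "leaf") return(row)
  dplyr::bind_rows(row,
                   walk_nodes(node$left, 2L * id),
                   walk_nodes(node$right, 2L * id + 1L))
}

#' @rdname fit_c45
#' @param x A `c45_tree`.
#' @param ... Unused.
#' @export
tidy.c45_tree <- function(x, ...) {
  nodes <- walk_nodes(x$root)
  nodes$feature <- ifelse(is.na(nodes$feature_index), NA_character_,
                          x$features[nodes$feature_index])
  nodes
}

#' @rdname fit_c45
#' @export
glance.c45_tree <- function(x, ...) {
  nodes <- walk_nodes(x$root)
  tibble(n_nodes = nrow(nodes),
         n_leaves = sum(nodes$type == "leaf"),
         depth = max(nodes$depth),
         n_train = x$root$n)
}

#' @export
print.c45_tree <- function(x, ...) {
  g <- glance(x)
  cat(sprintf("<c45_tree> %d nodes (%d leaves), depth %d, %d training samples\n",
              g$n_nodes, g$n_leaves, g$depth, g$n_train))
  invisible(x)
}
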