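# Fisher linear discriminant mapping of a feature table onto one dimension.

# Internal: fit on a numeric matrix + label factor. Returns weights (unit
# norm), projected class means, midpoint threshold, shrinkage actually used.
fit_lda_matrix <- function(x, labels, shrinkage = 1e-3) {
  labels <- as_label_factor(labels)
  if (any(table(labels) < 2)) abort("LDA needs at least 2 samples per class.")
  x1 <- x[labels == "MDD", , drop = FALSE]
  x2 <- x[labels == "HV", , drop = FALSE]
  mu1 <- colMeans(x1)
  mu2 <- colMeans(x2)
  sw <- crossprod(sweep(x1, 2, mu1)) + crossprod(sweep(x2, 2, mu2))
  d <- diag(sw)
  # guard against zero-variance features so diagonal shrinkage has an effect
  d[d == 0] <- if (any(d > 0)) mean(d[d > 0]) else 1
  lambda <- shrinkage
  w <- NULL
  repeat {
    reg <- sw + lambda * diag(d, nrow = ncol(x))
    w <- tryCatch(solve(reg, mu1 - mu2), error = function(e) NULL)
    if (!is.null(w) && all(is.finite(w))) break
    if (lambda >= 1) {
      warn("Within-class scatter singular; falling back to pseudoinverse.")
      w <- as.vector(MASS::ginv(reg) %*% (mu1 - mu2))
      break
    }
    lambda <- max(lambda, 1e-6) * 10
    warn(sprintf("Singular within-class scatter; increasing shrinkage to %g.", lambda))
  }
  nrm <- sqrt(sum(w^2))
  if (nrm > 0) w <- w / nrm
  p1 <- sum(w * mu1)
  p2 <- sum(w * mu2)
  if (p1 < p2) {  # canonical sign: MDD projects higher
    w <- -w
    p1 <- -p1
    p2 <- -p2
  }
  list(weights = w, mean_mdd = p1, mean_hv = p2,
       threshold = (p1 + p2) / 2, shrinkage = lambda)
}

#' Fit a Fisher linear discriminant mapping
#'
#' Computes the projection direction `w` proportional to
#' `(S_w + lambda * diag(S_w))^{-1} (mu_MDD - mu_HV)`, where `S_w` is the
#' pooled within-class scatter matrix. Diagonal shrinkage keeps the solve
#' well-posed when many features are selected relative to the sample count
#' (scatter matrices are near-singular in high dimension); if the regularized
#' system is still singular, shrinkage is escalated with a warning. The sign
#' is fixed so MDD projects higher, and the decision threshold is the
#' midpoint of the projected class means.
#'
#' @param train A feature table with both classes present.
#' @param shrinkage Diagonal shrinkage weight in `[0, 1]` (default 1e-3).
#' @return An `lda_map` object with `weights`, projected class means,
#'   `threshold`, and the projected training scores.
#' @examples
#' tab <- generate_feature_table(synth_config(n_mdd = 20, n_hv = 20, seed = 1))
#' fit <- fit_lda(tab)
#' head(tidy(fit))
#' @export
fit_lda <- function(train, shrinkage = 1e-3) {
  assert_feature_table(train)
  m <- ft_matrix(train)
  fit <- fit_lda_matrix(m, train$label, shrinkage)
  scores <- as.vector(m %*% fit$weights)
  structure(list(
    weights = setNames(fit$weights, colnames(m)),
    features = colnames(m),
    mean_mdd = fit$mean_mdd, mean_hv = fit$mean_hv,
    threshold = fit$threshold, shrinkage = fit$shrinkage,
    train_scores = tibble(sample_id = train$sample_id,
                          label = as_label_factor(train$label),
                          ld1 = scores)
  ), class = "lda_map")
}

#' Project a feature table onto the discriminant axis
#'
#' Maps each sample to a single feature `ld1`, the dot product with the
#' fitted weights; `sample_id` and `label` are carried through.
#'
#' @param table A feature table with exactly the model's features.
#' @param model An `lda_map` from [fit_lda()].
#' @return A feature table with the single feature column `ld1`.
#' @export
lda_transform <- function(table, model) {
  stopifnot(inherits(model, "lda_map"))
  assert_feature_table(table)
  feats <- feature_names(table)
  if (!setequal(feats, model$features)) {
    abort("Feature set does not match the fitted LDA model.")
  }
  m <- as.matrix(table[model$features])
  out <- tibble(sample_id = table$sample_id,
                label = as_label_factor(table$label),
                ld1 = as.vector(m %*% model$weights))
  set_value_kind(out, "normalized")
}

#' @export
predict.lda_map <- function(object, newdata, type = c("class", "score"), ...) {
  scores <- lda_transform(newdata, object)$ld1
  type <- match.arg(type)
  if (type == "score") return(scores)
  as_label_factor(ifelse(scores > object$threshold, "MDD", "HV"))
}

#' @export
print.lda_map <- function(x, ...) {
  cat(sprintf("<lda_map> %d features -> 1D; threshold %.4f (MDD mean %.4f, HV mean %.4f), shrinkage %g\n",
              length(x$weights), x$threshold, x$mean_mdd, x$mean_hv, x$shrinkage))
  invisible(x)
}

#' @rdname fit_lda
#' @param x,object An `lda_map`.
#' @param ... Unused.
#' @export
tidy.lda_map <- function(x, ...) {
  tibble(feature = names(x$weights), weight = unname(x$weights))
}

#' @rdname fit_lda
#' @export
glance.lda_map <- function(x, ...) {
  s <- x$train_scores
  pooled_sd <- sqrt(mean(tapply(s$ld1, s$label, var)))
  tibble(n_features = length(x$weights),
         threshold = x$threshold,
         mean_mdd = x$mean_mdd, mean_hv = x$mean_hv,
         separation = (x$mean_mdd - x$mean_hv) / pooled_sd,
         shrinkage = x$shrinkage)
}
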