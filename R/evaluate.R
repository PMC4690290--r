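# Confusion-matrix construction and diagnostic test metrics, with the
# convention that any zero denominator yields the sentinel Inf.

#' Build a 2x2 confusion matrix
#'
#' The positive class is MDD (depressed). Counts follow the diagnostic
#' convention: `A` true positives, `B` false positives (healthy predicted
#' depressed, "error healthy"), `C` false negatives (depressed predicted
#' healthy, "error depressed"), `D` true negatives.
#'
#' @param truth,estimate Vectors of labels in `{MDD, HV}`, equal length.
#' @return A `confusion` object with counts `A`, `B`, `C`, `D`.
#' @export
confusion <- function(truth, estimate) {
  if (length(truth) != length(estimate)) abort("`truth` and `estimate` lengths differ.")
  bad <- setdiff(unique(c(as.character(truth), as.character(estimate))), .classes)
  if (length(bad) > 0) {
    abort(paste0("Labels must be in {MDD, HV}; found: ", paste(bad, collapse = ", ")))
  }
  truth <- as_label_factor(truth)
  estimate <- as_label_factor(estimate)
  structure(list(
    A = sum(truth == "MDD" & estimate == "MDD"),
    B = sum(truth == "HV" & estimate == "MDD"),
    C = sum(truth == "MDD" & estimate == "HV"),
    D = sum(truth == "HV" & estimate == "HV")
  ), class = "confusion")
}

#' @export
print.confusion <- function(x, ...) {
  m <- matrix(c(x$A, x$C, x$B, x$D), 2, 2,
              dimnames = list(truth = .classes, predicted = .classes))
  print(m)
  invisible(x)
}

ratio_or_inf <- function(num, den) if (den == 0) Inf else num / den

#' Diagnostic metrics from a confusion matrix
#'
#' Computes the seven standard diagnostic-test quantities on the percent
#' scale: sensitivity `A/(A+C)*100`, specificity `D/(D+B)*100`, positive and
#' negative predictive values `A/(A+B)*100` and `D/(D+C)*100`, likelihood
#' ratios `LR+ = sensitivity/(100-specificity)` and
#' `LR- = (100-sensitivity)/specificity`, and accuracy `(A+D)/n*100`; plus
#' the error counts `error_depressed = C` and `error_healthy = B`. Any zero
#' denominator yields `Inf`.
#'
#' @param cm A `confusion` object.
#' @return A one-row `metrics_report` tibble.
#' @examples
#' cm <- confusion(rep(c("MDD", "HV"), c(5, 5)),
#'                 rep(c("MDD", "HV"), c(5, 5)))
#' diagnostic_metrics(cm)
#' @export
diagnostic_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion"))
  n <- cm$A + cm$B + cm$C + cm$D
  if (n == 0) abort("Empty confusion matrix.")
  sens <- ratio_or_inf(cm$A, cm$A + cm$C) * 100
  spec <- ratio_or_inf(cm$D, cm$D + cm$B) * 100
  out <- tibble(
    sensitivity = sens,
    specificity = spec,
    lr_pos = if (is.finite(sens)) ratio_or_inf(sens, 100 - spec) else Inf,
    lr_neg = if (is.finite(sens) && is.finite(spec)) ratio_or_inf(100 - sens, spec) else Inf,
    ppv = ratio_or_inf(cm$A, cm$A + cm$B) * 100,
    npv = ratio_or_inf(cm$D, cm$D + cm$C) * 100,
    accuracy = 100 * (cm$A + cm$D) / n,
    error_depressed = cm$C,
    error_healthy = cm$B
  )
  class(out) <- c("metrics_report", class(out))
  out
}

#' Format a metrics report the way result tables print it
#'
#' Percentages are rounded to integers and likelihood ratios to two
#' decimals; `Inf` prints literally. Full precision is kept in the
#' underlying report.
#'
#' @param metrics A `metrics_report`.
#' @return A one-row tibble of formatted character values.
#' @export
format_metrics <- function(metrics) {
  fmt_pct <- function(v) ifelse(is.finite(v), as.character(round(v)), "Inf")
  fmt_lr <- function(v) ifelse(is.finite(v), as.character(round(v, 2)), "Inf")
  tibble(
    sensitivity = fmt_pct(metrics$sensitivity),
    specificity = fmt_pct(metrics$specificity),
    lr_pos = fmt_lr(metrics$lr_pos),
    lr_neg = fmt_lr(metrics$lr_neg),
    ppv = fmt_pct(metrics$ppv),
    npv = fmt_pct(metrics$npv),
    accuracy = fmt_pct(metrics$accuracy),
    error_depressed = as.character(metrics$error_depressed),
    error_healthy = as.character(metrics$error_healthy)
  )
}
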