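# ggplot2 visualisations for fitted objects.

#' Plot the genetic-algorithm fitness history
#'
#' Best-ever, generation-best and generation-mean fitness across generations.
#'
#' @param object A `ga_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ga_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("best_ever", "best", "mean"),
                           names_to = "series", values_to = "fitness")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$generation, y = .data$fitness,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Generation", y = "Fitness (accuracy - feature penalty)",
                  colour = NULL, title = "GA feature-selection search") +
    ggplot2::theme_minimal()
}

#' Plot the discriminant projection of the training samples
#'
#' Density of the 1-D projected scores per class with the decision threshold.
#'
#' @param object An `lda_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.lda_map <- function(object, ...) {
  ggplot2::ggplot(object$train_scores,
                  ggplot2::aes(x = .data$ld1, fill = .data$label)) +
    ggplot2::geom_density(alpha = 0.5) +
    ggplot2::geom_vline(xintercept = object$threshold, linetype = "dashed") +
    ggplot2::labs(x = "Discriminant score", y = "Density", fill = NULL,
                  title = "Fisher LDA projection") +
    ggplot2::theme_minimal()
}

#' Plot the held-out diagnostic metrics of a run
#'
#' Bar chart of the percent-scale metrics of a `run_report`.
#'
#' @param object A `run_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.run_report <- function(object, ...) {
  m <- object$metrics
  d <- tibble(
    metric = factor(c("Sensitivity", "Specificity", "PPV", "NPV", "Accuracy"),
                    levels = c("Sensitivity", "Specificity", "PPV", "NPV", "Accuracy")),
    value = c(m$sensitivity, m$specificity, m$ppv, m$npv, m$accuracy)
  )
  d <- d[is.finite(d$value), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_cartesian(ylim = c(0, 100)) +
    ggplot2::labs(x = NULL, y = "Percent",
                  title = sprintf("Held-out performance (%s, %d features)",
                                  object$mode, object$n_features_after)) +
    ggplot2::theme_minimal()
}
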