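#' Plot an evaluation report
#'
#' Bar chart of precision, recall and F1 per stratum (intra, cross, all).
#'
#' @param object an `eval_report` from [evaluate_events()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.eval_report <- function(object, ...) {
  df <- tidyr::pivot_longer(tibble::as_tibble(object),
                            cols = c("precision", "recall", "f1"),
                            names_to = "metric", values_to = "value")
  df$stratum <- factor(df$stratum, levels = c("intra", "cross", "all"))
  df$metric <- factor(df$metric, levels = c("precision", "recall", "f1"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "%", fill = NULL,
                  title = "Lives_In extraction performance") +
    ggplot2::ylim(0, 100) +
    ggplot2::theme_minimal()
}

#' Plot per-sieve event counts
#'
#' Shows how the event set grows across the sieves (intra-clause patterns,
#' propagation, cross-clause trigger inference, cross-sentence inference).
#'
#' @param object a `lives_in_result` from [extract_events()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.lives_in_result <- function(object, ...) {
  df <- object$sieve_counts
  df$sieve <- factor(df$sieve, levels = df$sieve)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$sieve, y = .data$events)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "cumulative events",
                  title = paste0("Sieve progression: ", object$doc_id)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
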