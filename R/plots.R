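#' Histogram of term-drug character distances
#'
#' Shows the distribution of edge-to-edge character gaps across candidates
#' or alerts, with the pairing threshold marked.
#'
#' @param cands Candidates or alerts tibble with a `distance_chars` column.
#' @param max_distance Threshold to mark (default 43).
#' @return A ggplot object.
#' @export
plot_distance_distribution <- function(cands, max_distance = 43L) {
  ggplot2::ggplot(cands, ggplot2::aes(x = .data$distance_chars)) +
    ggplot2::geom_histogram(binwidth = 2, boundary = 0, fill = "steelblue",
                            colour = "white") +
    ggplot2::geom_vline(xintercept = max_distance, linetype = "dashed") +
    ggplot2::labs(x = "characters between ADR term and drug name",
                  y = "candidates") +
    ggplot2::theme_minimal()
}

#' Per-stage candidate counts of a pipeline run
#'
#' Visualizes the run report: how many candidates enter and leave each
#' pipeline and refinement stage.
#'
#' @param alerts Alerts tibble from [run_pipeline()].
#' @return A ggplot object.
#' @export
plot_stage_counts <- function(alerts) {
  rep <- run_report(alerts)
  rep$stage <- factor(rep$stage, levels = rep$stage)
  ggplot2::ggplot(rep, ggplot2::aes(x = .data$stage, y = .data$n_out)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_out), vjust = -0.3,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "rows after stage") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}
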