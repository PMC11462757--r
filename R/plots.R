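# ggplot2 views of the main result types: symmetry-score distributions per
# call class (the violin comparison used to contrast RNA-seq and WGS
# inputs), call-category bars, recurrence histograms and the autonomy
# rank-rank scatter with its diagonal split.

#' Symmetry-score distribution per call class
#'
#' @param calls Classified call tibble.
#' @param pass_only Restrict to PASS calls?
#' @return A ggplot (violin + jitter of symmetry scores by class, with the
#'   ideal 50% line).
#' @export
plot_symmetry_distribution <- function(calls, pass_only = TRUE) {
  tbl <- as_tibble(calls)
  if (pass_only && "pass" %in% names(tbl)) tbl <- tbl |> filter(.data$pass)
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$call_class, y = .data$symmetry,
                                    fill = .data$call_class)) +
    ggplot2::geom_violin(alpha = 0.6, show.legend = FALSE) +
    ggplot2::geom_jitter(width = 0.1, alpha = 0.4, size = 0.8, show.legend = FALSE) +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed") +
    ggplot2::scale_y_continuous(limits = c(0, 100)) +
    ggplot2::labs(x = NULL, y = "Symmetry score (%)",
                  title = "Split-read symmetry per call class") +
    ggplot2::theme_minimal()
}

#' Call-category counts
#'
#' @param calls Classified call tibble.
#' @param pass_only Restrict to PASS calls?
#' @return A ggplot bar chart of the three call classes.
#' @export
plot_call_categories <- function(calls, pass_only = TRUE) {
  props <- category_proportions(calls, pass_only = pass_only)
  ggplot2::ggplot(props, ggplot2::aes(x = .data$call_class, y = .data$n_calls,
                                      fill = .data$call_class)) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.0f%%", 100 * .data$fraction)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "Calls",
                  title = "Call categories") +
    ggplot2::theme_minimal()
}

#' Cross-sample recurrence histogram
#'
#' @param recurrence Result of [recurrence_across_samples()].
#' @return A ggplot histogram of how many samples support each merged call.
#' @export
plot_recurrence <- function(recurrence) {
  hist <- recurrence$histogram
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$n_samples, y = .data$n_calls)) +
    ggplot2::geom_col(fill = "grey30") +
    ggplot2::scale_x_continuous(breaks = hist$n_samples) +
    ggplot2::labs(x = "Samples supporting the call", y = "Calls",
                  title = "Call recurrence across samples") +
    ggplot2::theme_minimal()
}

#' Autonomy rank-rank scatter
#'
#' Consensus-expression rank against fusion-support rank per TE family; the
#' diagonal separates non-autonomous elements (fusion-dominated, upper half)
#' from autonomously expressed ones (lower half).
#'
#' @param object A `te_autonomy` result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.te_autonomy <- function(object, ...) {
  tbl <- object$elements
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$consensus_rank, y = .data$fusion_rank,
                                    colour = .data$label)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "TE consensus read rank", y = "TE-mRNA fusion support rank",
                  colour = NULL,
                  title = sprintf("TE autonomy (Spearman rho = %.2f)", object$spearman_rho)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
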