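#' Nested-loop plot of a simulation results grid
#'
#' Displays every scenario of a [run_grid()] results table in one panel per
#' missing mechanism, in the grid's nested ordering (sample size > missing
#' percentage > metabolite), one step line per imputation method. The
#' conventional way to show a factorial simulation study at a glance.
#'
#' @param results Tibble from [run_grid()].
#' @param metric Column to plot, default `"pct_bias"`.
#' @return A ggplot object.
#' @export
plot_nested_loop <- function(results, metric = "pct_bias") {
  if (!metric %in% colnames(results)) stop("no column '", metric, "'")
  df <- results
  df$scenario <- stats::ave(seq_len(nrow(df)),
                            interaction(df$mechanism, df$method),
                            FUN = seq_along)
  df$label <- sprintf("n=%d | %d%% | %s", df$n, round(100 * df$pct),
                      df$target_id)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$scenario, y = .data[[metric]],
                                   colour = .data$method)) +
    ggplot2::geom_step(linewidth = 0.4) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~mechanism, ncol = 1L) +
    ggplot2::labs(x = "scenario (n ⊃ missing % ⊃ metabolite)",
                  y = metric, colour = NULL) +
    ggplot2::theme_minimal(base_size = 10)
}
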