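#' @importFrom ggplot2 ggplot aes autoplot
NULL

#' Plot per-SST index performance (R-squared boxplots)
#'
#' One box per SST level over the valid per-iteration `R^2` values of the
#' fit of test-set index values to the pressure gradient.
#'
#' @param object An `sst_sweep`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sst_sweep <- function(object, ...) {
  d <- dplyr::filter(object$metrics, .data$valid)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$sst), y = .data$r2)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, fill = "grey85") +
    ggplot2::labs(x = "Sequence similarity threshold (%)",
                  y = expression(R^2 ~ "(index vs PC1, test set)")) +
    ggplot2::theme_minimal()
}

#' Plot the discrimination/stability trade-off
#'
#' Both curves min–max normalized to `[0, 1]` across the SST grid:
#' discrimination power (mean SD of index values within a randomization)
#' and stability SD (spread of that discrimination across randomizations;
#' higher = less stable).
#'
#' @param sweep An `sst_sweep` (or a tradeoff tibble from
#'   [summarize_tradeoff()]).
#' @return A ggplot.
#' @export
plot_tradeoff <- function(sweep) {
  d <- if (inherits(sweep, "sst_sweep")) summarize_tradeoff(sweep) else sweep
  long <- tidyr::pivot_longer(
    d[c("sst", "discrimination_norm", "stability_norm")],
    cols = -"sst", names_to = "curve", values_to = "value")
  long$curve <- dplyr::recode(long$curve,
                              discrimination_norm = "discrimination power",
                              stability_norm = "stability SD (less stable)")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sst, y = .data$value,
                                     colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.4) +
    ggplot2::labs(x = "Sequence similarity threshold (%)",
                  y = "normalized value (0-1)", colour = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "bottom")
}

#' Heat map of per-sample index variability across the SST grid
#'
#' Tiles show the SD of each sample's index values across randomizations;
#' samples are ordered by their overall mean index (poor to high quality).
#'
#' @param sweep An `sst_sweep`.
#' @return A ggplot.
#' @export
plot_sample_stability <- function(sweep) {
  d <- sweep$sample_stats
  ord <- d |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(m = mean(.data$mean_idx), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$m))
  d$sample <- factor(d$sample, levels = ord$sample)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$sst), y = .data$sample,
                                  fill = .data$sd_idx)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "#fff5f0", high = "#99000d",
                                 na.value = "grey90") +
    ggplot2::labs(x = "Sequence similarity threshold (%)", y = NULL,
                  fill = "SD of index") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
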