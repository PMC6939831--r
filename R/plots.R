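#' Plot a window scan along the genome
#'
#' Fst and ROD tracks per chromosome, with selected windows highlighted
#' when a [call_sweeps()] result is supplied.
#'
#' @param object A [scan_windows()] tibble.
#' @param sweep_call Optional `sweep_call` whose selected windows are
#'   drawn in red and thresholds as dashed lines.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot scan_windows
#' @export
autoplot.scan_windows <- function(object, sweep_call = NULL, ...) {
  df <- as_tibble(object) |>
    filter(.data$eligible) |>
    tidyr::pivot_longer(c("fst", "rod"), names_to = "statistic",
                        values_to = "value")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$start / 1e6,
                                        y = .data$value)) +
    ggplot2::geom_point(size = 0.4, colour = "grey40") +
    ggplot2::facet_grid(statistic ~ chrom, scales = "free") +
    ggplot2::labs(x = "position (Mb)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(sweep_call)) {
    sel <- as_tibble(sweep_call$selected) |>
      tidyr::pivot_longer(c("fst", "rod"), names_to = "statistic",
                          values_to = "value")
    thr <- tibble(statistic = c("fst", "rod"),
                  value = unname(sweep_call$thresholds[c("fst", "rod")]))
    p <- p +
      ggplot2::geom_point(data = sel, colour = "red", size = 0.6) +
      ggplot2::geom_hline(data = thr,
                          ggplot2::aes(yintercept = .data$value),
                          linetype = "dashed", colour = "red")
  }
  p
}

#' Joint Fst/ROD scatter of eligible windows
#'
#' The two-statistic view behind joint top-quantile selection: each point
#' is a window; the top-right corner past both dashed thresholds holds the
#' selected sweep windows.
#'
#' @param windows A [scan_windows()] tibble.
#' @param sweep_call Optional `sweep_call` providing thresholds and
#'   selection highlighting.
#' @return A ggplot object.
#' @export
plot_fst_rod <- function(windows, sweep_call = NULL) {
  df <- filter(as_tibble(windows), .data$eligible,
               !is.na(.data$fst), !is.na(.data$rod))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$rod, y = .data$fst)) +
    ggplot2::geom_point(size = 0.5, colour = "grey40", alpha = 0.6) +
    ggplot2::labs(x = "ROD", y = "Fst") +
    ggplot2::theme_minimal()
  if (!is.null(sweep_call)) {
    p <- p +
      ggplot2::geom_point(data = as_tibble(sweep_call$selected),
                          colour = "red", size = 0.7) +
      ggplot2::geom_vline(xintercept = sweep_call$thresholds[["rod"]],
                          linetype = "dashed") +
      ggplot2::geom_hline(yintercept = sweep_call$thresholds[["fst"]],
                          linetype = "dashed")
  }
  p
}

#' Plot an otolith Sr:Ca transect
#'
#' Core-to-edge ratios with the freshwater/brackish and brackish/seawater
#' thresholds as horizontal reference lines.
#'
#' @param object A transect tibble (`distance_um`, `sr_ca_ratio`).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot srca_transect
#' @export
autoplot.srca_transect <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$distance_um,
                               y = .data$sr_ca_ratio)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = c(3, 7), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::labs(x = "distance from core (um)", y = "Sr:Ca (x1000)") +
    ggplot2::theme_minimal()
}

#' Plot per-sample relative expression from a ddCt analysis
#'
#' @param object A `ddct_result` from [ddct_relative_expression()].
#' @param ... Unused.
#' @return A ggplot object (RQ by group, log2 scale).
#' @method autoplot ddct_result
#' @export
autoplot.ddct_result <- function(object, ...) {
  ggplot2::ggplot(object$samples,
                  ggplot2::aes(x = .data$group, y = .data$rq)) +
    ggplot2::geom_boxplot(outlier.shape = NA, fill = "grey90") +
    ggplot2::geom_jitter(width = 0.15, size = 1) +
    ggplot2::scale_y_continuous(trans = "log2") +
    ggplot2::labs(x = NULL, y = "relative quantity (2^-ddCt)",
                  title = object$gene) +
    ggplot2::theme_minimal()
}
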