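#' Sketch the uORF architecture of a 5'UTR
#'
#' Draws the UTR as a line from the cap to the main AUG with each uORF as a
#' labelled box, in cap-offset coordinates.
#'
#' @param utr A [utr_sequence()].
#' @param uorfs Optional precomputed [scan_uorfs()] table.
#' @return A ggplot.
#' @export
plot_utr_architecture <- function(utr, uorfs = scan_uorfs(utr)) {
  L <- utr_length(utr)
  p <- ggplot2::ggplot() +
    ggplot2::annotate("segment", x = 0, xend = L - 1, y = 0, yend = 0,
                      linewidth = 1) +
    ggplot2::annotate("point", x = L, y = 0, shape = 17, size = 3) +
    ggplot2::annotate("text", x = L, y = 0.25, label = "mAUG", size = 3) +
    ggplot2::scale_y_continuous(NULL, breaks = NULL, limits = c(-0.8, 1.2)) +
    ggplot2::labs(x = "distance from 5' cap (nt)") +
    ggplot2::theme_minimal()
  if (nrow(uorfs)) {
    boxes <- uorfs |>
      dplyr::mutate(
        label = sprintf("uORF%d (%s, %s)", .data$uorf, .data$peptide,
                        .data$frame_vs_morf)
      )
    p <- p +
      ggplot2::geom_rect(
        data = boxes,
        ggplot2::aes(xmin = .data$start_offset, xmax = .data$end_offset,
                     ymin = -0.2, ymax = 0.2, fill = factor(.data$uorf)),
        colour = "black", show.legend = FALSE
      ) +
      ggplot2::geom_text(
        data = boxes,
        ggplot2::aes(x = (.data$start_offset + .data$end_offset) / 2,
                     y = -0.5, label = .data$label),
        size = 3
      )
  }
  p
}
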