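#' Tumour-by-chromosome SCNA event matrix plot
#'
#' Tile plot of event categories per tumour and chromosome, the standard
#' cohort-overview rendering of an SCNA catalogue. Where a tumour carries
#' several events on one chromosome the most severe category is shown
#' (GCR > AMP/DEL > whole > partial).
#'
#' @param events Event tibble with `tumour_id`, `chrom`, `category`.
#' @param layout Optional [genome_layout()] fixing chromosome order.
#' @return A ggplot object.
#' @export
plot_scna_matrix <- function(events, layout = NULL) {
  severity <- c(GCR = 7, AMP = 6, DEL = 5, WCG = 4, WCL = 3, PCG = 2,
                PCL = 1)
  palette <- c(DEL = "#1b7837", AMP = "#a6dba0", WCG = "#4d4d4d",
               WCL = "#bababa", PCG = "#2166ac", PCL = "#92c5de",
               GCR = "#b2182b")
  top <- events %>%
    dplyr::mutate(sev = severity[.data$category]) %>%
    dplyr::group_by(.data$tumour_id, .data$chrom) %>%
    dplyr::slice_max(.data$sev, n = 1, with_ties = FALSE) %>%
    dplyr::ungroup()
  chrom_levels <- if (is.null(layout)) unique(events$chrom) else layout$chrom
  top <- dplyr::mutate(top,
                       chrom = factor(.data$chrom, levels = chrom_levels))
  ggplot2::ggplot(top, ggplot2::aes(x = .data$chrom, y = .data$tumour_id,
                                    fill = .data$category)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::scale_fill_manual(values = palette, drop = FALSE) +
    ggplot2::labs(x = NULL, y = NULL, fill = "SCNA") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Amplicon overlap plot with minimal common region
#'
#' Draws each tumour's amplicon as a horizontal bar (shaded by segment
#' mean when available) and overlays the minimal common region, the view
#' used to show that recurrent amplicons share a driver locus.
#'
#' @param amplicons Tibble with `tumour_id`, `chrom`, `start_bp`, `end_bp`
#'   and optionally `mean_log2`.
#' @param mcr Optional one-row region from [minimal_common_region()].
#' @return A ggplot object.
#' @export
plot_amplicon_overlap <- function(amplicons, mcr = NULL) {
  has_mean <- "mean_log2" %in% names(amplicons)
  p <- ggplot2::ggplot(amplicons)
  if (!is.null(mcr) && nrow(mcr) == 1) {
    p <- p + ggplot2::annotate("rect", xmin = mcr$start_bp / 1e6,
                               xmax = mcr$end_bp / 1e6, ymin = -Inf,
                               ymax = Inf, fill = "gold", alpha = 0.3)
  }
  aes_seg <- if (has_mean) {
    ggplot2::aes(x = .data$start_bp / 1e6, xend = .data$end_bp / 1e6,
                 y = .data$tumour_id, yend = .data$tumour_id,
                 colour = .data$mean_log2)
  } else {
    ggplot2::aes(x = .data$start_bp / 1e6, xend = .data$end_bp / 1e6,
                 y = .data$tumour_id, yend = .data$tumour_id)
  }
  p <- p + ggplot2::geom_segment(aes_seg, linewidth = 3)
  if (has_mean) {
    p <- p + ggplot2::scale_colour_gradient2(low = "steelblue",
                                             mid = "grey85",
                                             high = "firebrick",
                                             midpoint = 0)
  }
  p + ggplot2::labs(x = "position (Mb)", y = NULL, colour = "segment mean") +
    ggplot2::theme_minimal()
}

#' Per-chromosome SCNA frequency bar plot
#'
#' @param freq Output of [per_chromosome_frequency()].
#' @return A ggplot object.
#' @export
plot_chromosome_frequency <- function(freq) {
  totals <- freq %>%
    dplyr::group_by(.data$chrom, .data$genotype) %>%
    dplyr::summarise(fraction = max(.data$fraction), .groups = "drop")
  ggplot2::ggplot(totals, ggplot2::aes(x = .data$chrom, y = .data$fraction,
                                       fill = .data$genotype)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(labels = function(x) paste0(100 * x, "%")) +
    ggplot2::labs(x = NULL, y = "tumours affected") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
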