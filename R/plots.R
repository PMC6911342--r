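# ggplot2 views of the result objects: read-depth profiles (with optional
# precursor/mature/ORF annotations), per-tissue LC histograms, and the
# paired-tissue LC comparison.

#' Plot a read-depth profile
#'
#' @param object A `coverage_profile`.
#' @param precursor,mature Optional length-2 intervals (0-based half-open)
#'   drawn as shaded boxes.
#' @param orfs Optional ORF tibble from [find_orfs()], drawn as segments.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.coverage_profile <- function(object, precursor = NULL, mature = NULL,
                                      orfs = NULL, ...) {
  df <- as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$depth)) +
    ggplot2::geom_area(fill = "grey35") +
    ggplot2::labs(x = "position in contig (nt)", y = "reads covering position",
                  title = object$contig_id) +
    ggplot2::theme_minimal()
  shade <- function(p, iv, fill) {
    p + ggplot2::annotate("rect", xmin = iv[1], xmax = iv[2], ymin = -Inf,
                          ymax = Inf, alpha = 0.25, fill = fill)
  }
  if (!is.null(precursor)) p <- shade(p, precursor, "orange")
  if (!is.null(mature)) p <- shade(p, mature, "red")
  if (!is.null(orfs) && nrow(orfs) > 0) {
    p <- p + ggplot2::annotate("segment", x = orfs$start, xend = orfs$end,
                               y = 0, yend = 0, linewidth = 2,
                               colour = "steelblue")
  }
  p
}

#' @rdname lc_distribution
#' @param object An `lc_distribution`.
#' @export
autoplot.lc_distribution <- function(object, ...) {
  df <- object$histogram
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_start + object$bin_width / 2,
                                   y = .data$count)) +
    ggplot2::geom_col(width = object$bin_width * 0.9, fill = "grey40") +
    ggplot2::labs(x = "local coverage (LC)", y = "contig count",
                  title = object$tissue,
                  subtitle = sprintf("Shapiro-Wilk W = %s, p = %s",
                                     format(object$W, digits = 4),
                                     format(object$p_value, digits = 3))) +
    ggplot2::theme_minimal()
}

#' @rdname compare_tissues
#' @param object A `tissue_comparison`.
#' @export
autoplot.tissue_comparison <- function(object, ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(c("leaf_lc", "phloem_lc"), names_to = "tissue",
                        values_to = "lc") |>
    mutate(tissue = sub("_lc$", "", .data$tissue))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tissue, y = .data$lc,
                                   group = .data$query_id,
                                   colour = .data$class)) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::geom_line(na.rm = TRUE, alpha = 0.5) +
    ggplot2::geom_hline(yintercept = attr(object, "lc_threshold"),
                        linetype = "dashed") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "local coverage (LC, log scale)",
                  colour = "mobility class") +
    ggplot2::theme_minimal()
}
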