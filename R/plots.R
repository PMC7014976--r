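#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL

#' Plot an eigen (compartment) track
#'
#' Per-bin eigenvector values as bars coloured by A/B label, faceted by
#' chromosome.
#' @param object An `eigen_track`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eigen_track <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df[!is.na(df$eigen), ],
                  ggplot2::aes(x = .data$start / 1e6, y = .data$eigen,
                               fill = .data$label)) +
    ggplot2::geom_col(width = attr(object, "genome")$resolution / 1e6) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::scale_fill_manual(values = c(A = "#d73027", B = "#4575b4"),
                               na.value = "grey70") +
    ggplot2::labs(x = "position (Mb)", y = "PC1", fill = "compartment") +
    ggplot2::theme_minimal()
}

#' Plot an insulation track with called boundaries
#' @param object An `insulation_track`.
#' @param boundaries Optional tibble with `chrom`, `bin` to mark.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.insulation_track <- function(object, boundaries = NULL, ...) {
  df <- tibble::as_tibble(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$start / 1e6, y = .data$score)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = "insulation (log2)") +
    ggplot2::theme_minimal()
  if (!is.null(boundaries) && nrow(boundaries) > 0) {
    res <- attr(object, "genome")$resolution
    p <- p + ggplot2::geom_vline(
      data = boundaries,
      ggplot2::aes(xintercept = .data$bin * res / 1e6),
      colour = "#d73027", linetype = 2, alpha = 0.6)
  }
  p
}

#' Plot an APA aggregate
#' @param object An `apa_result`.
#' @param ... Unused.
#' @return A ggplot object (O/E heat map with the score in the title).
#' @export
autoplot.apa_result <- function(object, ...) {
  k <- object$half_window
  df <- expand.grid(di = -k:k, dj = -k:k)
  df$oe <- as.vector(object$matrix)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dj, y = .data$di, fill = .data$oe)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(midpoint = 1, low = "#4575b4",
                                  mid = "white", high = "#d73027") +
    ggplot2::labs(title = sprintf("APA score %.2f (n = %d)", object$score, object$n_used),
                  x = "offset (bins)", y = "offset (bins)", fill = "O/E") +
    ggplot2::theme_minimal()
}

#' MD plot of a pixel pair table
#'
#' Log ratio M against distance D with the loess fit (if the table has
#' been normalized) overlaid.
#' @param t A `pixel_pair_table`.
#' @param alpha Point alpha (default 0.2).
#' @return A ggplot object.
#' @export
plot_md <- function(t, alpha = 0.2) {
  stopifnot(inherits(t, "pixel_pair_table"))
  p <- ggplot2::ggplot(tibble::as_tibble(t),
                       ggplot2::aes(x = .data$D, y = .data$M)) +
    ggplot2::geom_point(alpha = alpha, size = 0.4) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "distance D (bins)", y = "M = log2 ratio") +
    ggplot2::theme_minimal()
  if ("M_fit" %in% names(t)) {
    p <- p + ggplot2::geom_line(ggplot2::aes(y = .data$M_fit), colour = "#d73027")
  }
  p
}

#' Bar chart of enrichment results
#' @param object A tibble of `enrichment_result` rows (with a `class`
#'   column).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_result <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- sprintf("p = %.2g", df$p)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$class, y = .data$fold)) +
    ggplot2::geom_col(fill = "#74add1") +
    ggplot2::geom_hline(yintercept = 1, linetype = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "fold enrichment") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Heat map of a contact or O/E matrix region
#' @param m A `contact_matrix` or `oe_matrix`.
#' @param chrom Chromosome to draw.
#' @param value Column to plot (default `count` or `oe`).
#' @param log Log10-transform the fill (default TRUE for counts).
#' @return A ggplot object.
#' @export
plot_matrix <- function(m, chrom, value = NULL, log = NULL) {
  if (is.null(value)) value <- if ("oe" %in% names(m)) "oe" else "count"
  if (is.null(log)) log <- value == "count"
  df <- tibble::as_tibble(m)
  df <- df[df$chrom == chrom, , drop = FALSE]
  df <- dplyr::bind_rows(df, stats::setNames(df[df$bin1 != df$bin2, ],
                                             names(df)[c(1, 3, 2, 4)]))
  df$fill <- if (log) log10(df[[value]] + 1) else df[[value]]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin2, y = .data$bin1,
                                   fill = .data$fill)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "bin", y = "bin",
                  fill = if (log) paste0("log10 ", value) else value) +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}
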