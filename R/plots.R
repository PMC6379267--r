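#' Manhattan plot of a genome scan
#'
#' @param scan A `scan_result`.
#' @param thresholds Optional `threshold_set`; drawn as dashed lines.
#' @return A ggplot object.
#' @export
plot_manhattan <- function(scan, thresholds = NULL) {
  df <- as_tibble(scan)
  df$chrom <- factor(df$chrom, levels = unique(df$chrom))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$pos / 1e6,
                                        y = .data$neg_log10_p,
                                        colour = .data$chrom)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chrom), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10] * p)) +
    ggplot2::theme_minimal()
  if (!is.null(thresholds)) {
    p <- p + ggplot2::geom_hline(yintercept = unname(thresholds$thresholds),
                                 linetype = "dashed", colour = "grey30")
  }
  p
}

#' @rdname plot_manhattan
#' @param object A `scan_result`.
#' @param ... Unused.
#' @export
autoplot.scan_result <- function(object, ...) plot_manhattan(object)

#' Krzanowski subspace profile plot
#'
#' Shared-subspace eigenvalues against the number of retained eigenvectors,
#' one line per eigenvalue rank.
#'
#' @param profile Tibble from [krzanowski_profile()].
#' @param max_rank Show only the first `max_rank` eigenvalue ranks.
#' @return A ggplot object.
#' @export
plot_subspace_profile <- function(profile, max_rank = 6L) {
  df <- dplyr::filter(profile, .data$rank <= max_rank)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$k, y = .data$Delta,
                                   colour = factor(.data$rank))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::labs(x = "eigenvectors retained per matrix (k)",
                  y = expression(Delta), colour = "rank") +
    ggplot2::theme_minimal()
}

#' Heritability spectrum plot
#'
#' @param spectrum A `heritability_spectrum`.
#' @return A ggplot object.
#' @export
plot_heritability_spectrum <- function(spectrum) {
  ggplot2::ggplot(as_tibble(spectrum),
                  ggplot2::aes(x = .data$rank, y = .data$eigenvalue)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "direction (ranked)", y = expression(h^2)) +
    ggplot2::theme_minimal()
}

#' @rdname plot_heritability_spectrum
#' @param object A `heritability_spectrum`.
#' @param ... Unused.
#' @export
autoplot.heritability_spectrum <- function(object, ...) {
  plot_heritability_spectrum(object)
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
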