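# ggplot2 autoplot methods for the main result types.

#' @describeIn hg_pca Scatter plot of the first two principal components.
#' @param object An `hg_pca` object.
#' @exportS3Method ggplot2::autoplot
autoplot.hg_pca <- function(object, ...) {
  sc <- object$scores
  ggplot2::ggplot(sc, ggplot2::aes(.data$PC1, .data$PC2,
                                   label = .data$population)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$var_fraction[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$var_fraction[2]),
      title = "Covariance PCA of haplogroup composition") +
    ggplot2::theme_minimal()
}

#' @describeIn hg_nmds Scatter plot of the MDS configuration.
#' @param object An `hg_nmds` object.
#' @param ... Unused.
#' @exportS3Method ggplot2::autoplot
autoplot.hg_nmds <- function(object, ...) {
  co <- object$coordinates
  ggplot2::ggplot(co, ggplot2::aes(.data$MDS1, .data$MDS2,
                                   label = .data$population)) +
    ggplot2::geom_point() +
    ggplot2::geom_text(vjust = -0.6, size = 3) +
    ggplot2::labs(title = sprintf("Non-metric MDS (stress %.1f%%)",
                                  object$stress_percent)) +
    ggplot2::theme_minimal()
}

#' @describeIn build_rm_network Network layout plot; node area is
#'   proportional to haplotype multiplicity, inferred median nodes are drawn
#'   hollow.
#' @param object An `rm_network` object.
#' @exportS3Method ggplot2::autoplot
autoplot.rm_network <- function(object, ...) {
  set.seed(1)
  xy <- igraph::layout_with_fr(object$graph,
                               weights = igraph::E(object$graph)$steps)
  nd <- object$nodes
  nd$x <- xy[, 1]; nd$y <- xy[, 2]
  ed <- tidy.rm_network(object)
  ed$x <- nd$x[ed$from]; ed$y <- nd$y[ed$from]
  ed$xend <- nd$x[ed$to]; ed$yend <- nd$y[ed$to]
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = ed,
                          ggplot2::aes(x = .data$x, y = .data$y,
                                       xend = .data$xend, yend = .data$yend),
                          colour = "grey50") +
    ggplot2::geom_point(data = nd,
                        ggplot2::aes(.data$x, .data$y,
                                     size = pmax(.data$multiplicity, 0.5),
                                     shape = .data$inferred)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 1)) +
    ggplot2::scale_size_area(max_size = 8) +
    ggplot2::labs(title = "Reduced-median haplotype network",
                  size = "count", shape = "inferred") +
    ggplot2::theme_void()
}

#' @describeIn sample_split_posterior Posterior density of the split times.
#' @param object A `split_posterior` object.
#' @exportS3Method ggplot2::autoplot
autoplot.split_posterior <- function(object, ...) {
  sc <- grep("^split", names(object$samples), value = TRUE)
  long <- tidyr::pivot_longer(object$samples[, sc], dplyr::all_of(sc),
                              names_to = "split", values_to = "years")
  ggplot2::ggplot(long, ggplot2::aes(.data$years / 1000,
                                     colour = .data$split)) +
    ggplot2::geom_density() +
    ggplot2::labs(x = "split time (Kya)", y = "posterior density",
                  title = "Population split-time posterior") +
    ggplot2::theme_minimal()
}

#' Skree plot of PCA eigenvalue fractions
#'
#' @param p An `hg_pca` object.
#' @param k Number of components to show.
#' @return A ggplot object.
#' @export
plot_skree <- function(p, k = 10) {
  d <- head(tidy.hg_pca(p), k)
  ggplot2::ggplot(d, ggplot2::aes(.data$component, 100 * .data$var_fraction)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = p$skree_k + 0.5, linetype = 2) +
    ggplot2::labs(x = "component", y = "% variance",
                  title = "Eigenvalue fractions (skree)") +
    ggplot2::theme_minimal()
}
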