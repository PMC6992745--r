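#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a genotype PCA
#' @param x A `genotype_pca`.
#' @param ... Unused.
#' @return Long tibble: `sample`, `component`, `coordinate`.
#' @export
tidy.genotype_pca <- function(x, ...) {
  tidyr::pivot_longer(x$coordinates, -"sample", names_to = "component",
                      values_to = "coordinate")
}

#' @rdname tidy.genotype_pca
#' @export
glance.genotype_pca <- function(x, ...) {
  tibble::tibble(n_samples = nrow(x$coordinates),
                 n_sites_used = x$n_sites_used,
                 pc1 = x$explained_fraction[1],
                 pc2 = x$explained_fraction[2],
                 pc3 = x$explained_fraction[3])
}

#' Tidy a pairwise fixation-index estimate
#' @param x An `fst_estimate`.
#' @param ... Unused.
#' @return Per-locus tibble of variance components `a` (among-population)
#'   and `d` (total), plus the per-locus ratio.
#' @export
tidy.fst_estimate <- function(x, ...) {
  dplyr::mutate(x$loci, theta_locus = .data$a / .data$d)
}

#' @rdname tidy.fst_estimate
#' @export
glance.fst_estimate <- function(x, ...) {
  tibble::tibble(theta = x$theta, n_loci_used = x$n_loci_used,
                 n_loci_skipped = x$n_loci_skipped, estimator = x$estimator)
}

#' Tidy an ancestry estimate
#' @param x An `ancestry_estimate`.
#' @param ... Unused.
#' @return Tibble with `group`, `q`.
#' @export
tidy.ancestry_estimate <- function(x, ...) {
  tibble::tibble(group = names(x$q), q = unname(x$q))
}

#' @rdname tidy.ancestry_estimate
#' @export
glance.ancestry_estimate <- function(x, ...) {
  tibble::tibble(loglik = x$loglik, iterations = x$iterations,
                 converged = x$converged, uninformative = x$uninformative)
}

#' PCA scatter plot (PC1 vs PC2)
#' @param object A `genotype_pca`.
#' @param groups Optional named vector sample -> group for colouring.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.genotype_pca <- function(object, groups = NULL, ...) {
  df <- object$coordinates
  lab <- function(i) sprintf("PC%d (%.1f%%)", i,
                             100 * object$explained_fraction[i])
  p <- if (!is.null(groups)) {
    df$group <- unname(groups[df$sample])
    ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                     colour = .data$group))
  } else {
    ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2))
  }
  p + ggplot2::geom_point() +
    ggplot2::labs(x = lab(1), y = lab(2)) + ggplot2::theme_minimal()
}

#' Stacked ancestry-fraction bars
#' @param object An `ancestry_table` from [estimate_ancestry_all()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ancestry_table <- function(object, ...) {
  long <- tidyr::pivot_longer(object, dplyr::starts_with("q_"),
                              names_to = "group", values_to = "q",
                              names_prefix = "q_")
  ggplot2::ggplot(long, ggplot2::aes(.data$sample, .data$q,
                                     fill = .data$group)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::facet_grid(~sampled_group, scales = "free_x", space = "free_x") +
    ggplot2::labs(x = NULL, y = "ancestry fraction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       size = 6))
}

#' Within-group fixation-index distributions
#' @param object An `fst_within` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fst_within <- function(object, ...) {
  means <- fst_within_means(object)
  ggplot2::ggplot(object, ggplot2::aes(.data$group, .data$theta)) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.4, size = 0.8) +
    ggplot2::geom_point(data = means,
                        ggplot2::aes(.data$group, .data$mean_theta),
                        shape = 4, size = 4, colour = "red") +
    ggplot2::labs(y = "pairwise theta between accessions") +
    ggplot2::theme_minimal()
}
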