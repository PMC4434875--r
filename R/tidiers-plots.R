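#' Tidy PCA scores into a long tibble
#'
#' @param x an `srna_pca` object.
#' @param ... unused.
#' @return tibble: `sample`, `component`, `score`.
#' @export
tidy.srna_pca <- function(x, ...) {
  x$scores |>
    tidyr::pivot_longer(-"sample", names_to = "component",
                        values_to = "score")
}

#' One-row PCA summary
#'
#' @param x an `srna_pca` object.
#' @param ... unused.
#' @return tibble with sample/feature counts and leading variance fractions.
#' @export
glance.srna_pca <- function(x, ...) {
  tibble(
    n_samples = nrow(x$scores),
    n_features = nrow(x$loadings),
    pc1_variance = x$variance_fraction[1],
    pc2_variance = if (length(x$variance_fraction) > 1) {
      x$variance_fraction[2]
    } else NA_real_,
    dropped_features = length(x$dropped_features)
  )
}

#' Tidy a sample dendrogram's merge history
#'
#' @param x an `srna_dendro` (hclust) object.
#' @param ... unused.
#' @return tibble: `merge`, `height`, plus the ordered leaf labels as the
#'   `leaf_order` attribute.
#' @export
tidy.srna_dendro <- function(x, ...) {
  out <- tibble(merge = seq_along(x$height), height = x$height)
  attr(out, "leaf_order") <- x$labels[x$order]
  out
}

#' Plot a library size-class profile
#'
#' @param profile tibble from [size_profile_and_qc()] (`$profile`).
#' @return a ggplot: abundance per insert length with the 21/24 nt classes
#'   highlighted.
#' @export
plot_size_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$length, y = .data$abundance,
                               fill = .data$length %in% c(21, 24))) +
    ggplot2::geom_col(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c("grey60", "#2c7fb8")) +
    ggplot2::labs(x = "insert length (nt)", y = "abundance (TP5M)") +
    ggplot2::theme_minimal()
}

#' @describeIn pca_samples autoplot method: sample scores on the first two
#'   components, labelled with variance fractions.
#' @param object an `srna_pca` object.
#' @param colour optional vector (length = samples) used to colour points.
#' @param ... unused.
#' @export
autoplot.srna_pca <- function(object, colour = NULL, ...) {
  df <- object$scores
  if (!is.null(colour)) df$colour <- colour
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$PC1, y = .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$variance_fraction[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$variance_fraction[2])) +
    ggplot2::theme_minimal()
  if (is.null(colour)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour)) +
      ggplot2::labs(colour = NULL)
  }
}

#' Heatmap of a sample-averaged abundance matrix
#'
#' Expression is shown as log10(1 + TP5M) tiles, miRNAs ordered by total
#' abundance.
#'
#' @param avg_mat wide tibble `mirna_id` + sample columns.
#' @return a ggplot.
#' @export
plot_atlas_heatmap <- function(avg_mat) {
  samples <- setdiff(names(avg_mat), "mirna_id")
  long <- avg_mat |>
    tidyr::pivot_longer(all_of(samples), names_to = "sample",
                        values_to = "tp5m") |>
    mutate(value = log10(1 + .data$tp5m))
  ord <- long |> group_by(.data$mirna_id) |>
    summarise(tot = sum(.data$tp5m)) |> arrange(.data$tot) |> pull("mirna_id")
  long |>
    mutate(mirna_id = factor(.data$mirna_id, levels = ord),
           sample = factor(.data$sample, levels = samples)) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$sample, y = .data$mirna_id,
                                 fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "#d7301f",
                                 name = "log10(1+TP5M)") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
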