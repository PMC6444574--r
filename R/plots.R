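# ggplot2 figures for each result type.

#' Plot a composition profile
#'
#' Bar panels for the small-RNA class composition (if present) and the
#' mature-derived tsRNA type fractions.
#'
#' @param object A `tsrna_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tsrna_profile <- function(object, ...) {
  ty <- object$type_fractions |> mutate(panel = "tsRNA type")
  dat <- ty |> rename(label = "ts_class")
  if (!is.null(object$class_fractions)) {
    cl <- object$class_fractions |>
      mutate(panel = "small-RNA class") |>
      rename(label = "rna_class")
    dat <- bind_rows(cl, dat)
  }
  ggplot2::ggplot(dat, ggplot2::aes(
    x = stats::reorder(.data$label, -.data$fraction),
    y = 100 * .data$fraction
  )) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~panel, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "% of weighted reads") +
    ggplot2::theme_minimal()
}

#' Length distribution histogram
#'
#' @param records tsRNA records, or a length histogram tibble from
#'   [length_distribution()].
#' @param type Optional tsRNA class to restrict to.
#' @return A ggplot object.
#' @export
plot_length_distribution <- function(records, type = NULL) {
  hist <- if (all(c("length", "weight", "ts_class") %in% names(records)) &&
    !"tag_sequence" %in% names(records)) {
    records
  } else {
    length_distribution(records, type)
  }
  if (!is.null(type)) hist <- filter(hist, .data$ts_class == type)
  ggplot2::ggplot(hist, ggplot2::aes(x = .data$length, y = 100 * .data$fraction)) +
    ggplot2::geom_col(fill = "firebrick") +
    ggplot2::facet_wrap(~ts_class) +
    ggplot2::labs(x = "fragment length (nt)", y = "% of type weight") +
    ggplot2::theme_minimal()
}

#' Replicate scatter with Pearson r annotation
#'
#' log2(CPM + 1) of two samples over the union of species, with the
#' Pearson correlation printed on the panel.
#'
#' @inheritParams replicate_correlation
#' @return A ggplot object.
#' @export
plot_replicate_scatter <- function(counts, sample_a, sample_b, library_sizes = NULL) {
  r <- replicate_correlation(counts, sample_a, sample_b, library_sizes)
  wide <- counts |>
    filter(.data$sample_id %in% c(sample_a, sample_b)) |>
    cpm_normalize(library_sizes) |>
    select("species_key", "sample_id", "cpm") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "cpm", values_fill = 0)
  ggplot2::ggplot(wide, ggplot2::aes(
    x = log2(.data[[sample_a]] + 1), y = log2(.data[[sample_b]] + 1)
  )) +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::annotate("text",
      x = -Inf, y = Inf, hjust = -0.2, vjust = 1.5,
      label = sprintf("R = %.3f", r)
    ) +
    ggplot2::labs(
      x = sprintf("%s log2(CPM+1)", sample_a),
      y = sprintf("%s log2(CPM+1)", sample_b)
    ) +
    ggplot2::theme_minimal()
}

#' Volcano plot of a differential-expression result
#'
#' @param object A `tsrna_de`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tsrna_de <- function(object, ...) {
  ggplot2::ggplot(object$results, ggplot2::aes(
    x = .data$log2_fold_change, y = -log10(pmax(.data$q_value, 1e-300)),
    colour = .data$call
  )) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::scale_colour_manual(
      values = c(up = "firebrick", down = "steelblue", ns = "grey60")
    ) +
    ggplot2::labs(x = "log2 fold change (case / control)", y = "-log10 q") +
    ggplot2::theme_minimal()
}

#' Clustered heatmap of differentially expressed species
#'
#' Row-scaled log2(CPM + 1) of the DE-called species across samples, rows
#' and columns ordered by hierarchical clustering - the standard two-group
#' DE heatmap.
#'
#' @param counts Long count tibble.
#' @param de A `tsrna_de`.
#' @param samples Sample sheet tibble.
#' @param library_sizes Optional per-sample library sizes.
#' @return A ggplot object.
#' @export
plot_de_heatmap <- function(counts, de, samples, library_sizes = NULL) {
  calls <- call_de(de)
  keys <- c(calls$up, calls$down)
  if (length(keys) < 2) abort_msg("fewer than 2 DE species to draw")
  wide <- counts |>
    filter(.data$species_key %in% keys) |>
    cpm_normalize(library_sizes) |>
    select("species_key", "sample_id", "cpm") |>
    tidyr::pivot_wider(names_from = "sample_id", values_from = "cpm", values_fill = 0)
  mat <- log2(as.matrix(wide[, -1]) + 1)
  rownames(mat) <- wide$species_key
  mat <- t(scale(t(mat)))
  row_ord <- stats::hclust(stats::dist(mat))$order
  col_ord <- stats::hclust(stats::dist(t(mat)))$order
  long <- as_tibble(mat, rownames = "species_key") |>
    tidyr::pivot_longer(-"species_key", names_to = "sample_id", values_to = "z") |>
    mutate(
      species_key = factor(.data$species_key, levels = rownames(mat)[row_ord]),
      sample_id = factor(.data$sample_id, levels = colnames(mat)[col_ord])
    )
  ggplot2::ggplot(long, ggplot2::aes(.data$sample_id, .data$species_key, fill = .data$z)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick") +
    ggplot2::labs(x = NULL, y = NULL, fill = "row z") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5))
}
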