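#' Plot a region profile as a median z-score heatmap
#'
#' @param object a `region_profile`.
#' @param genes optional subset of genes to show (default: regional genes).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.region_profile <- function(object, genes = NULL, ...) {
  genes <- genes %||% object$gene_ids[rowSums(object$regional) > 0]
  df <- tidy.region_profile(object) |>
    filter(.data$gene_id %in% genes) |>
    mutate(region = factor(.data$region, levels = object$regions))
  ggplot(df, aes(x = .data$region, y = .data$gene_id, fill = .data$median_z)) +
    geom_tile() +
    scale_fill_gradient2(low = "steelblue", mid = "white", high = "firebrick",
                         midpoint = 0, na.value = "grey85") +
    labs(x = "region (anterior → posterior)", y = NULL,
         fill = "median z") +
    theme_minimal()
}

#' Plot a specimen's z-score profiles along the A-P axis
#'
#' @param object a `z_profile`.
#' @param genes genes to draw (e.g. markers).
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.z_profile <- function(object, genes, ...) {
  df <- tidy.z_profile(object) |>
    filter(.data$gene_id %in% genes) |>
    mutate(section = match(.data$section_id, object$section_ids))
  ggplot(df, aes(x = .data$section, y = .data$z, colour = .data$gene_id)) +
    ggplot2::geom_line() +
    labs(x = "section (anterior → posterior)", y = "z-score",
         colour = NULL) +
    theme_minimal()
}

#' Stacked-bar plot of phylostratum composition
#'
#' @param composition tibble from [age_composition()].
#' @return a ggplot with one stacked bar per gene set ("Ref" first).
#' @export
plot_age_composition <- function(composition) {
  sets <- unique(composition$set)
  df <- composition |>
    mutate(set = factor(.data$set, levels = sets),
           stratum = factor(.data$stratum, levels = rev(sort(unique(.data$stratum)))))
  ggplot(df, aes(x = .data$set, y = .data$fraction, fill = .data$stratum)) +
    geom_col() +
    labs(x = NULL, y = "fraction of genes", fill = "phylostratum") +
    theme_minimal()
}

#' Region-overlap significance heatmap
#'
#' @param overlaps tibble from [region_overlap_tests()].
#' @return a ggplot tile map of shared counts shaded by -log10(q).
#' @export
plot_overlap_heatmap <- function(overlaps) {
  df <- overlaps |>
    mutate(neglog10_q = -log10(pmax(.data$q, .Machine$double.xmin)))
  ggplot(df, aes(x = .data$region_b, y = .data$region_a,
                 fill = .data$neglog10_q)) +
    geom_tile() +
    ggplot2::geom_text(aes(label = .data$k), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    labs(x = NULL, y = NULL, fill = expression(-log[10] * q)) +
    theme_minimal()
}

#' Boxplot-style summary of dN/dS by group
#'
#' Draws the median and interquartile range per group from a rate summary.
#'
#' @param rate_summary tibble from [summarize_rates()].
#' @return a ggplot.
#' @export
plot_rate_summary <- function(rate_summary) {
  df <- rate_summary |>
    filter(.data$n > 0) |>
    mutate(group = factor(.data$group, levels = unique(.data$group)))
  ggplot(df, aes(x = .data$group, y = .data$median_omega)) +
    geom_pointrange(aes(ymin = .data$q1, ymax = .data$q3)) +
    labs(x = NULL, y = "dN/dS (median, IQR)") +
    theme_minimal()
}
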