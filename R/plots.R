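# ggplot2 figures: a lollipop-style domain map of classified variants, and
# a proportion plot for the enrichment contrast.

CLASS_COLOURS <- c(
  "Pathogenic" = "#c0392b", "Likely pathogenic" = "#e67e22",
  "VUS" = "#2980b9", "Likely benign" = "#27ae60", "Benign" = "#1e8449"
)

#' Domain map of the protein with variant lollipops
#'
#' Draws the top-level domain architecture as a track and places each
#' span-bearing variant as a lollipop at its residue position, coloured by
#' classification when a `chd4_classification` table is supplied.
#'
#' @param variants A variant tibble.
#' @param classified Optional `chd4_classification` for the same variants.
#' @param arch Domain architecture.
#' @param protein_length Protein residue bound.
#' @return A ggplot object.
#' @export
plot_domain_map <- function(variants, classified = NULL,
                            arch = chd4_domains(),
                            protein_length = CHD4_LENGTH) {
  top <- dplyr::filter(arch, .data$role == "domain")
  v <- dplyr::filter(variants, !is.na(.data$residue_start))
  v$classification <- if (!is.null(classified)) {
    classified$classification[match(v$variant, classified$variant)]
  } else {
    "VUS"
  }
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = tibble::tibble(x = 1, xend = protein_length),
      ggplot2::aes(x = .data$x, xend = .data$xend, y = 0, yend = 0),
      linewidth = 0.4, colour = "grey60"
    ) +
    ggplot2::geom_rect(
      data = top,
      ggplot2::aes(xmin = .data$start, xmax = .data$end,
                   ymin = -0.25, ymax = 0.25, fill = .data$name),
      colour = "grey30", show.legend = FALSE, alpha = 0.6
    ) +
    ggplot2::geom_segment(
      data = v,
      ggplot2::aes(x = .data$residue_start, xend = .data$residue_start,
                   y = 0.25, yend = 1),
      linewidth = 0.3, colour = "grey40"
    ) +
    ggplot2::geom_point(
      data = v,
      ggplot2::aes(x = .data$residue_start, y = 1,
                   colour = .data$classification),
      size = 2
    ) +
    ggplot2::scale_colour_manual(values = CLASS_COLOURS, name = NULL) +
    ggplot2::scale_y_continuous(limits = c(-0.4, 1.3), breaks = NULL) +
    ggplot2::labs(x = "residue", y = NULL) +
    ggplot2::theme_minimal()
}

#' @describeIn plot_domain_map autoplot method for classification tables;
#'   requires `residue_start` to be joinable from `variants`.
#' @param object A `chd4_classification` tibble.
#' @param variants The variant tibble the classification came from.
#' @param ... Passed on to [plot_domain_map()].
#' @export
autoplot.chd4_classification <- function(object,
                                         variants = chd4_variants(), ...) {
  plot_domain_map(variants, classified = object, ...)
}

#' Proportion plot for an enrichment result
#'
#' Shows the heart-anomaly proportion in each group with the exact test's
#' p-value and the Katz odds-ratio interval in the subtitle.
#'
#' @param object A `chd4_enrichment` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chd4_enrichment <- function(object, ...) {
  tab <- object$table
  df <- tibble::tibble(
    group = rownames(tab),
    yes = tab[, "yes"], total = rowSums(tab)
  ) |>
    dplyr::mutate(proportion = .data$yes / .data$total)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$proportion)) +
    ggplot2::geom_col(fill = "#2980b9", width = 0.5) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = NULL, y = "proportion with heart anomaly",
      subtitle = sprintf("Fisher p = %.3g; OR = %.3g (%.3g-%.3g)",
                         object$p_two_sided, object$odds_ratio,
                         object$ci_low, object$ci_high)
    ) +
    ggplot2::theme_minimal()
}
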