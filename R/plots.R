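#' Plot per-sample category expression percentages
#'
#' One dot per sample per category (jittered), with the across-sample mean
#' drawn as a crossbar — the standard presentation of per-category expressed
#' fractions.
#'
#' @param object A `category_profile` from [category_percentages()].
#' @param ... Unused.
#' @returns A ggplot object.
#' @export
autoplot.category_profile <- function(object, ...) {
  df <- dplyr::filter(object, .data$level == "category")
  df$group <- factor(df$group, levels = matrisome_categories)
  means <- df |>
    group_by(.data$group) |>
    summarise(mean_pct = mean(.data$pct), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$group, y = .data$pct)) +
    ggplot2::geom_jitter(width = 0.15, height = 0, alpha = 0.7) +
    ggplot2::geom_crossbar(
      data = means,
      ggplot2::aes(y = .data$mean_pct, ymin = .data$mean_pct,
                   ymax = .data$mean_pct),
      width = 0.5, linewidth = 0.4) +
    ggplot2::scale_y_continuous(limits = c(0, 100)) +
    ggplot2::labs(x = NULL, y = "Expressed genes (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot paired marker co-expression ratios per gene
#'
#' Per-sample ratios against the two markers, side by side per gene, lines
#' joining the paired values within a sample.
#'
#' @param object A `coexpr_results` from [run_coexpression()].
#' @param ... Unused.
#' @returns A ggplot object.
#' @export
autoplot.coexpr_results <- function(object, ...) {
  markers <- attr(object, "markers") %||% c("markerA", "markerB")
  ratios <- coexpr_ratio_table(object) |>
    tidyr::pivot_longer(c("ratio_a", "ratio_b"),
                        names_to = "marker", values_to = "ratio") |>
    mutate(marker = ifelse(.data$marker == "ratio_a", markers[1], markers[2]))
  ggplot2::ggplot(ratios,
                  ggplot2::aes(x = .data$marker, y = 100 * .data$ratio)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$sample_id),
                       alpha = 0.4, na.rm = TRUE) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$marker), na.rm = TRUE) +
    ggplot2::facet_wrap(~gene) +
    ggplot2::labs(x = NULL, y = "Co-expression (%)") +
    ggplot2::guides(shape = "none") +
    ggplot2::theme_minimal()
}

#' Plot cohort per-cell label proportions
#'
#' Cohort mean proportion per label class with SEM error bars.
#'
#' @param object A `cell_summary` from [summarize_cell_calls()].
#' @param ... Unused.
#' @returns A ggplot object.
#' @export
autoplot.cell_summary <- function(object, ...) {
  df <- object$cohort
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label, y = 100 * .data$mean_prop)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = 100 * (.data$mean_prop - .data$sem_prop),
                   ymax = 100 * (.data$mean_prop + .data$sem_prop)),
      width = 0.2, na.rm = TRUE) +
    ggplot2::labs(x = NULL, y = "Cells (%)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
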