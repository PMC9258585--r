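#' Plot a colony array as a heatmap
#'
#' @param plates Validated plate table.
#' @param plate_id Plate to show; defaults to the first.
#' @return A ggplot tile map of colony sizes (missing positions blank).
#' @export
plot_plate <- function(plates, plate_id = NULL) {
  plate_id <- plate_id %||% plates$plate[1]
  one <- dplyr::filter(plates, .data$plate == plate_id)
  ggplot2::ggplot(one, ggplot2::aes(
    x = .data$col, y = .data$row, fill = .data$size
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90") +
    ggplot2::coord_fixed() +
    ggplot2::labs(
      title = plate_id, x = "Column", y = "Row", fill = "Colony size"
    )
}

#' Volcano-style plot of interaction scores
#'
#' Mean interaction score against -log10 BH-adjusted p-value, with the
#' calling thresholds drawn and calls coloured.
#'
#' @param records Called interaction records (see [call_interactions()]).
#' @param eps_threshold,q_threshold Thresholds to draw (defaults match
#'   [call_interactions()]).
#' @return A ggplot.
#' @export
plot_interaction_scores <- function(records, eps_threshold = -0.2,
                                    q_threshold = 0.05) {
  df <- dplyr::filter(records, .data$scorable)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$eps_mean, y = -log10(pmax(.data$q_bh, 1e-300)),
    colour = .data$call
  )) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::geom_vline(
      xintercept = c(eps_threshold, -eps_threshold), linetype = "dashed"
    ) +
    ggplot2::geom_hline(yintercept = -log10(q_threshold), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(
      negative = "firebrick", positive = "dodgerblue3", none = "grey60"
    )) +
    ggplot2::labs(
      x = expression(epsilon == W[AB] - W[A] * W[B]),
      y = expression(-log[10] ~ "BH q-value"),
      colour = "Call"
    )
}

#' Plot dose-response profiles
#'
#' Relative synthetic effect of each strain across the three mistranslation
#' levels, coloured by response category when available.
#'
#' @param rel Output of [relative_synthetic_effect()].
#' @param categories Optional output of [classify_profiles()] to colour by
#'   category.
#' @return A ggplot.
#' @export
plot_dose_response <- function(rel, categories = NULL) {
  df <- dplyr::mutate(rel, level = factor(.data$level, levels = dose_levels))
  if (!is.null(categories)) {
    df <- dplyr::left_join(
      df, dplyr::select(categories, "strain", "category"),
      by = "strain"
    )
    aes <- ggplot2::aes(
      x = .data$level, y = .data$rel_pct, group = .data$strain,
      colour = .data$category
    )
  } else {
    aes <- ggplot2::aes(
      x = .data$level, y = .data$rel_pct, group = .data$strain
    )
  }
  ggplot2::ggplot(df, aes) +
    ggplot2::geom_hline(yintercept = 100, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = "Mistranslation level",
      y = "Normalized growth (% of wild-type strain)",
      colour = "Category"
    )
}

#' Plot fitted growth curves for a table of OD series
#'
#' @param od OD tibble (`strain`, optional `replicate`, `time_min`, `od`).
#' @param fits Optional output of [fit_growth_curves()]; fitted curves are
#'   overlaid where converged.
#' @return A ggplot faceted by strain.
#' @export
plot_growth_curves <- function(od, fits = NULL) {
  if (!"replicate" %in% names(od)) od$replicate <- 1L
  p <- ggplot2::ggplot(od, ggplot2::aes(
    x = .data$time_min, y = .data$od,
    group = interaction(.data$strain, .data$replicate)
  )) +
    ggplot2::geom_point(size = 0.5, alpha = 0.5) +
    ggplot2::facet_wrap(ggplot2::vars(.data$strain)) +
    ggplot2::labs(x = "Time (min)", y = "OD600")
  if (!is.null(fits)) {
    ok <- dplyr::filter(fits, .data$converged)
    grid <- ok |>
      dplyr::group_by(.data$strain, .data$replicate) |>
      dplyr::reframe(
        time_min = seq(min(od$time_min), max(od$time_min), length.out = 100),
        od = .data$K / (1 + ((.data$K - .data$N0) / .data$N0) *
          exp(-.data$r * .data$time_min))
      )
    p <- p + ggplot2::geom_line(data = grid, colour = "steelblue")
  }
  p
}
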