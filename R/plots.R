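# ggplot2 displays of the three main outputs: observed vs estimated
# seeds-per-container series, the escape x survival sweep surface, and the
# stage-flow chain behind alluvial-style summaries.

#' Plot observed and KNN-estimated seeds per container over a season
#'
#' @param series Per-date observed rate series (from [aggregate_samples()]).
#' @param estimate An [estimate_total_influx()] result for the same taxon;
#'   optional -- omit to plot observations alone.
#' @return A ggplot object: observed rates as points, per-arrival-date KNN
#'   predictions as a line.
#' @export
plot_influx <- function(series, estimate = NULL) {
  p <- ggplot2::ggplot(series, ggplot2::aes(x = .data$date, y = .data$seeds_per_container)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = "Date", y = "Seeds per container",
      title = if (!is.null(estimate)) {
        sprintf("%s: estimated total influx %s seeds", estimate$taxon,
          format(estimate$N_rounded, big.mark = ","))
      } else {
        unique(as.character(series$taxon))[1]
      }
    ) +
    ggplot2::theme_minimal()
  if (!is.null(estimate)) {
    p <- p + ggplot2::geom_line(
      data = estimate$predictions,
      ggplot2::aes(x = .data$date, y = .data$s_hat),
      colour = "steelblue"
    )
  }
  p
}

#' Heatmap of invaded sites after four years over a sweep grid
#'
#' Cells whose swept survival rate exceeds the empirically observed
#' survivorship are outlined (they represent conditions more favourable
#' than measured).
#'
#' @param sweep A [run_sweep()] result.
#' @param sites Which carrying capacity to display (default: the largest).
#' @return A ggplot object faceted by taxon and season.
#' @export
plot_sweep <- function(sweep, sites = max(sweep$sites)) {
  x <- sweep[sweep$sites == sites, , drop = FALSE]
  ggplot2::ggplot(x, ggplot2::aes(
    x = factor(.data$escape), y = factor(.data$survival_used),
    fill = .data$invaded_after_4y
  )) +
    ggplot2::geom_tile(ggplot2::aes(
      colour = .data$v_above_observed,
      linewidth = ifelse(.data$v_above_observed, 0.6, 0)
    )) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "grey40", `FALSE` = NA), guide = "none"
    ) +
    ggplot2::scale_linewidth_identity() +
    ggplot2::scale_fill_viridis_c(name = "Invaded sites\nafter 4 years") +
    ggplot2::facet_grid(taxon ~ season) +
    ggplot2::labs(x = "Escape rate", y = "Survival rate") +
    ggplot2::theme_minimal()
}

#' Stage-flow bar chart at a fixed escape rate
#'
#' Shows, on a log scale, how the year-1 seed influx is whittled down by
#' escape, germination and survival, and the seed output of the resulting
#' established individuals.
#'
#' @param flow A [stage_flow_report()] result.
#' @param year Which simulated year to display (default 1).
#' @return A ggplot object faceted by taxon and season.
#' @export
plot_stage_flow <- function(flow, year = 1) {
  x <- flow[flow$year == year, , drop = FALSE] |>
    tidyr::pivot_longer(
      c("seeds_influx", "seeds_escaped", "germinated", "survived", "seeds_reproduced"),
      names_to = "stage", values_to = "count"
    )
  x$stage <- factor(x$stage, levels = c(
    "seeds_influx", "seeds_escaped", "germinated", "survived", "seeds_reproduced"
  ))
  ggplot2::ggplot(x, ggplot2::aes(x = .data$stage, y = pmax(.data$count, 0.1))) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::scale_y_log10(name = "Count (log scale)") +
    ggplot2::facet_grid(taxon ~ season) +
    ggplot2::labs(x = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
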