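# ggplot2 displays --------------------------------------------------------

#' Plot size-class mortality probability curves
#'
#' Smoothed mean probability of mortality (+/- 1 smoothed SD ribbon) across
#' the severity gradient, one panel per species group, coloured by DBH size
#' class.
#'
#' @param curves Tibble from [species_curves()] (one or more species).
#' @return A ggplot object.
#' @export
plot_mortality_curves <- function(curves) {
  ggplot2::ggplot(
    curves,
    ggplot2::aes(
      x = .data$severity, y = .data$smooth_mean,
      colour = factor(.data$dbh_class), fill = factor(.data$dbh_class)
    )
  ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(
        ymin = pmax(.data$smooth_mean - .data$smooth_sd, 0),
        ymax = pmin(.data$smooth_mean + .data$smooth_sd, 1)
      ),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::facet_wrap(ggplot2::vars(.data$species_group)) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Burn severity (RdNBR)", y = "Probability of mortality",
      colour = "DBH class (cm)", fill = "DBH class (cm)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot restorative severity ranges
#'
#' Horizontal severity intervals per forest x forest type, faceted by
#' metric, with line thickness by probability threshold.
#'
#' @param ranges Range tibble from [restorative_ranges()].
#' @return A ggplot object.
#' @export
plot_restorative_ranges <- function(ranges) {
  d <- ranges[!ranges$empty, ]
  d$group <- paste(d$forest, d$forest_type)
  ggplot2::ggplot(
    d,
    ggplot2::aes(
      y = .data$group, yend = .data$group,
      x = .data$lo, xend = .data$hi,
      colour = factor(.data$threshold)
    )
  ) +
    ggplot2::geom_segment(
      ggplot2::aes(linewidth = factor(.data$threshold)),
      lineend = "round", alpha = 0.8
    ) +
    ggplot2::scale_linewidth_manual(
      values = c("0.5" = 5, "0.75" = 3, "0.9" = 1.5), guide = "none"
    ) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric), ncol = 1) +
    ggplot2::labs(
      x = "Burn severity (RdNBR)", y = NULL,
      colour = "Restoration probability"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the per-severity fraction of stands within the HRV
#'
#' @param proportions Tibble from [restoration_proportions()].
#' @param thresholds Reference lines (default 0.9, 0.75, 0.5).
#' @return A ggplot object.
#' @export
plot_restoration_proportions <- function(proportions, thresholds = c(0.9, 0.75, 0.5)) {
  ggplot2::ggplot(proportions, ggplot2::aes(x = .data$severity, y = .data$fraction)) +
    ggplot2::geom_hline(
      yintercept = thresholds, linetype = "dashed",
      colour = "grey60"
    ) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(
      x = "Burn severity (RdNBR)",
      y = "Fraction of simulated stands within HRV"
    ) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Map a restoration class raster
#'
#' Cool colours below the restorative window, yellow within it, warm
#' colours above; masked pixels in grey.
#'
#' @param object A `restoration_class_map` from [classify_pixels()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot restoration_class_map
#' @export
autoplot.restoration_class_map <- function(object, ...) {
  d <- tidy(object)
  d$class <- factor(d$class, levels = c(RESTORATION_CLASSES, "masked"))
  pal <- c(
    too_cold_lt50 = "#2166ac", cold_50_to_75 = "#92c5de",
    restorative_ge75 = "#ffd92f", hot_50_to_75 = "#f4a582",
    too_hot_lt50 = "#b2182b", masked = "grey80"
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$col, y = -.data$row, fill = .data$class)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_manual(values = pal, drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "Restoration class") +
    ggplot2::theme_void()
}
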