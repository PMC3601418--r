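#' Tidy and glance methods
#'
#' Broom-style accessors for the package's result objects: `tidy()` returns
#' the per-unit table (per compartment, grid cell, ...) as a plain tibble;
#' `glance()` returns a one-row summary.
#'
#' @param x A `fate_result`, `ratio_map` or `bioacc_scan`.
#' @param ... Unused.
#' @return A tibble.
#' @name climfate-tidiers
NULL

#' @rdname climfate-tidiers
#' @method tidy fate_result
#' @export
tidy.fate_result <- function(x, ...) as_tibble(x)

#' @rdname climfate-tidiers
#' @method glance fate_result
#' @export
glance.fate_result <- function(x, ...) {
  budget <- attr(x, "loss_budget")
  tibble(
    inventory_mol = attr(x, "inventory_mol"),
    P_OV_h = attr(x, "P_OV_h"),
    degradation_mol_h = budget[["degradation_mol_h"]],
    advection_mol_h = budget[["advection_mol_h"]]
  )
}

#' @rdname climfate-tidiers
#' @method tidy ratio_map
#' @export
tidy.ratio_map <- function(x, ...) as_tibble(x)

#' @rdname climfate-tidiers
#' @method glance ratio_map
#' @export
glance.ratio_map <- function(x, ...) {
  summarize_ratios(x) |>
    filter(.data$region == "all") |>
    select("max_fold", "median_abs_dev_pct", "frac_within_20pct")
}

#' @rdname climfate-tidiers
#' @method tidy bioacc_scan
#' @export
tidy.bioacc_scan <- function(x, ...) as_tibble(x)

#' @rdname climfate-tidiers
#' @method glance bioacc_scan
#' @export
glance.bioacc_scan <- function(x, ...) {
  x |>
    group_by(.data$offset_C) |>
    summarise(
      max_increase_pct = 100 * (max(.data$max_ratio_spring_autumn) - 1),
      max_summer_fold_decrease = 1 / min(.data$min_ratio_summer),
      .groups = "drop"
    )
}

#' Heat-map of a climate/baseline ratio map
#'
#' Tiles of the perturbed-to-baseline concentration ratio over the
#' partitioning space, faceted by region and output, on a log2 color scale
#' centred at 1 (blue = reduced under the scenario, red = elevated).
#'
#' @param object A `ratio_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ratio_map
#' @export
autoplot.ratio_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$logKOA, .data$logKAW,
                                       fill = log2(.data$ratio))) +
    ggplot2::geom_raster() +
    ggplot2::facet_grid(region ~ output) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  name = "log2 ratio") +
    ggplot2::labs(x = "log KOA", y = "log KAW") +
    ggplot2::theme_minimal()
}

#' Seasonal-extreme map of a bioaccumulation scan
#'
#' @param object A `bioacc_scan`.
#' @param metric Which summary to map.
#' @param ... Unused.
#' @return A ggplot of tiles over log KOW x biotransformation half-life,
#'   faceted by warming offset.
#' @method autoplot bioacc_scan
#' @export
autoplot.bioacc_scan <- function(object,
                                 metric = c("max_ratio_spring_autumn",
                                            "min_ratio_summer",
                                            "max_ratio_annual",
                                            "min_ratio_annual"),
                                 ...) {
  metric <- match.arg(metric)
  ggplot2::ggplot(object, ggplot2::aes(.data$logKOW, log10(.data$HL_B_d),
                                       fill = log2(.data[[metric]]))) +
    ggplot2::geom_tile() +
    ggplot2::facet_wrap(~offset_C, labeller = ggplot2::label_both) +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0,
                                  name = paste0("log2 ", metric)) +
    ggplot2::labs(x = "log KOW", y = "log10 biotransformation half-life (d)") +
    ggplot2::theme_minimal()
}

#' Trajectory plot for a bioaccumulation simulation
#'
#' @param object A `bioacc_trajectory`.
#' @param what Variable to plot against time.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot bioacc_trajectory
#' @export
autoplot.bioacc_trajectory <- function(object,
                                       what = c("conc_mol_g", "weight_g",
                                                "temp_C"),
                                       ...) {
  what <- match.arg(what)
  ggplot2::ggplot(object, ggplot2::aes(.data$day, .data[[what]])) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "day", y = what) +
    ggplot2::theme_minimal()
}
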