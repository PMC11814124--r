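#' Map a pixel-level variable on the world grid
#'
#' @param pixels Pixel table with centroids.
#' @param fill Column to map to fill (tidy-eval); default protection status.
#' @return A ggplot.
#' @export
plot_world <- function(pixels, fill = NULL) {
  fill <- rlang::enquo(fill)
  if (rlang::quo_is_null(fill)) fill <- rlang::quo(.data$protection_status)
  ggplot2::ggplot(pixels,
                  ggplot2::aes(.data$centroid_lon, .data$centroid_lat)) +
    ggplot2::geom_tile(ggplot2::aes(fill = !!fill)) +
    ggplot2::geom_point(data = pixels[pixels$has_diving, ],
                        shape = 4, size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "longitude", y = "latitude",
                  caption = "crosses mark dive pixels") +
    ggplot2::theme_minimal()
}

#' Map the percent biomass change over dive pixels
#'
#' @param result A `scenario_result` from [run_scenario()].
#' @param pixels The bundle's pixel table (for centroids).
#' @return A ggplot.
#' @export
plot_biomass_change <- function(result, pixels) {
  stopifnot(inherits(result, "scenario_result"))
  df <- dplyr::inner_join(result$biomass$per_pixel,
                          pixels[, c("pixel_id", "centroid_lon",
                                     "centroid_lat")],
                          by = "pixel_id")
  ggplot2::ggplot(df, ggplot2::aes(.data$centroid_lon, .data$centroid_lat,
                                   fill = .data$pct_change)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "% biomass change") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "longitude", y = "latitude") +
    ggplot2::theme_minimal()
}

#' Plot fee-sweep curves (fee revenue, industry revenue, consumer surplus,
#' dives) for both policy branches
#'
#' @param object A `dive_fee_sweep` from [fee_sweep()].
#' @param ... Unused.
#' @return A ggplot, faceted by outcome.
#' @export
autoplot.dive_fee_sweep <- function(object, ...) {
  long <- object |>
    dplyr::select("policy", "fee_usd", "fee_revenue_usd",
                  "delta_industry_revenue_usd",
                  "delta_consumer_surplus_usd", "delta_dives") |>
    tidyr::pivot_longer(-c("policy", "fee_usd"),
                        names_to = "outcome", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$fee_usd, .data$value,
                                     colour = .data$policy)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~outcome, scales = "free_y") +
    ggplot2::labs(x = "dive fee (USD per dive)", y = NULL,
                  colour = "policy") +
    ggplot2::theme_minimal()
}

#' Plot the per-pixel change in dives of a scenario
#'
#' @param object A `scenario_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.scenario_result <- function(object, ...) {
  ggplot2::ggplot(object$pixels,
                  ggplot2::aes(.data$q_star, .data$delta_q,
                               colour = .data$is_upgraded)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "baseline dives per year",
                  y = "change in dives per year",
                  colour = "upgraded to MPA") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
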