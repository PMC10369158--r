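#' Map an environment stack variable
#'
#' @param object An [env_stack()].
#' @param variable Variable to map (default the first).
#' @param ... Unused.
#' @return A ggplot raster map.
#' @export
autoplot.env_stack <- function(object, variable = env_vars(object)$variable[1],
                               ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  fill = .data[[variable]])) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(name = variable) +
    ggplot2::labs(x = "x (m)", y = "y (m)")
}

#' Marginal response curves of a fitted model
#'
#' @param model A `maxent_model`.
#' @param variables Which variables (default all in the model's stack).
#' @param n_points,type Passed to [marginal_response()].
#' @return A faceted ggplot of suitability against each variable.
#' @export
plot_response_curves <- function(model,
                                 variables = model$expansion$variables,
                                 n_points = 100, type = "cloglog") {
  d <- purrr::map_dfr(variables, function(v) {
    dplyr::mutate(marginal_response(model, v, n_points, type), variable = v)
  })
  ggplot2::ggplot(d, ggplot2::aes(.data$value, .data$suitability)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~variable, scales = "free_x") +
    ggplot2::labs(x = NULL, y = paste0("suitability (", type, ")"))
}

#' Plot the group comparison of summed category importance
#'
#' @param object A `group_comparison_report`.
#' @param ... Unused.
#' @return A ggplot boxplot of summed permutation importance per predictor
#'   category, split by Red List status.
#' @export
autoplot.group_comparison_report <- function(object, ...) {
  cat_cols <- intersect(c("land_use_importance", "climate_importance",
                          "soil_importance"), names(object$summaries))
  d <- object$summaries |>
    dplyr::select(dplyr::all_of(c("species", "dutch_status", cat_cols))) |>
    tidyr::pivot_longer(dplyr::all_of(cat_cols), names_to = "category",
                        values_to = "importance") |>
    dplyr::mutate(category = sub("_importance$", "", .data$category))
  ggplot2::ggplot(d, ggplot2::aes(.data$category, .data$importance,
                                  fill = .data$dutch_status)) +
    ggplot2::geom_boxplot(position = ggplot2::position_dodge()) +
    ggplot2::labs(x = NULL, y = "summed permutation importance (%)",
                  fill = "status")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
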