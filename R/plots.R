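# ggplot2 views of the main result types.

#' Coding-quality heatmap
#'
#' Country-by-year tiles coloured by quality bin, one facet per nonspecific
#' category.
#'
#' @param quality Output of [assess_quality()].
#' @return A ggplot object.
#' @export
plot_quality <- function(quality) {
  ggplot2::ggplot(
    quality |> filter(!is.na(.data$bin)),
    ggplot2::aes(x = factor(.data$year), y = .data$country, fill = .data$bin)
  ) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::facet_wrap(ggplot2::vars(.data$category), nrow = 1) +
    ggplot2::scale_fill_brewer(
      palette = "YlOrRd",
      labels = c("0-20%", "21-40%", "41-60%", "61-80%", "81-100%"),
      drop = FALSE
    ) +
    ggplot2::labs(x = "Year", y = NULL, fill = "Nonspecific share") +
    ggplot2::theme_minimal()
}

#' Corrected vs uncorrected rate changes
#'
#' Distribution of the percent change in age-standardized mortality after
#' correction, by scope, with the +50% reference line.
#'
#' @param rates Output of [user_specific_rates()].
#' @return A ggplot object.
#' @export
plot_rate_changes <- function(rates) {
  ggplot2::ggplot(
    rates |> filter(is.finite(.data$pct_change)),
    ggplot2::aes(x = .data$scope, y = .data$pct_change)
  ) +
    ggplot2::geom_boxplot(outlier.alpha = 0.4) +
    ggplot2::geom_hline(yintercept = 50, linetype = "dashed", colour = "red") +
    ggplot2::labs(x = NULL,
                  y = "Rate change after correction (%)") +
    ggplot2::theme_minimal()
}

#' Projection scatter
#'
#' Projected 2021-2030 percent change per country, uncorrected vs corrected,
#' with the -50% on-track boundary.
#'
#' @param projections The `projections` element of [run_pipeline()] output.
#' @return A ggplot object.
#' @export
plot_projections <- function(projections) {
  pct_col <- grep("^pct_change_", names(projections), value = TRUE)[1]
  wide <- projections |>
    select(all_of(c("country", "corrected", pct_col))) |>
    tidyr::pivot_wider(names_from = "corrected",
                       values_from = all_of(pct_col),
                       names_prefix = "corrected_")
  ggplot2::ggplot(wide, ggplot2::aes(x = .data$corrected_FALSE,
                                     y = .data$corrected_TRUE)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey70") +
    ggplot2::geom_hline(yintercept = -50, linetype = "dashed", colour = "red") +
    ggplot2::geom_vline(xintercept = -50, linetype = "dashed", colour = "red") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "Projected change 2021-2030, uncorrected (%)",
                  y = "Projected change 2021-2030, corrected (%)") +
    ggplot2::theme_minimal()
}

#' @describeIn redistribute Bar chart of redistributed and unallocated mass
#'   by garbage category.
#' @param object An `rt_redistribution`.
#' @export
autoplot.rt_redistribution <- function(object, ...) {
  moved <- object$provenance |>
    group_by(.data$category) |>
    summarise(mass = sum(.data$added), .groups = "drop") |>
    mutate(status = "redistributed")
  lost <- object$unallocated |>
    group_by(.data$category) |>
    summarise(mass = sum(.data$mass), .groups = "drop") |>
    mutate(status = "unallocated")
  ggplot2::ggplot(bind_rows(moved, lost),
                  ggplot2::aes(x = factor(.data$category,
                                          levels = GARBAGE_CATEGORIES),
                               y = .data$mass, fill = .data$status)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "Deaths", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
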