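# Data-availability and coding-quality indicators.

QUALITY_BINS <- c("P0_20", "P21_40", "P41_60", "P61_80", "P81_100")

#' Data availability by country
#'
#' Counts, for each country, the number of years in `year_range` with at
#' least one death row. Countries passed in `countries` but absent from the
#' table report 0 years.
#'
#' @param table A mortality table.
#' @param year_range Vector of years defining the assessment window
#'   (default 2015-2020).
#' @param countries Universe of countries to report on; defaults to those
#'   present in the table.
#' @return Tibble `country, years_available`.
#' @export
assess_availability <- function(table, year_range = 2015:2020,
                                countries = NULL) {
  table <- mortality_table(table)
  countries <- countries %||% sort(unique(table$country))
  counts <- table |>
    filter(.data$year %in% year_range) |>
    distinct(.data$country, .data$year) |>
    dplyr::count(.data$country, name = "years_available")
  tibble(country = countries) |>
    left_join(counts, by = "country") |>
    mutate(years_available = tidyr::replace_na(.data$years_available, 0L))
}

#' Coding-quality proportions for the five nonspecific categories
#'
#' For each (country, year) and nonspecific category, the percentage of the
#' category's hierarchy-level deaths carrying a nonspecific code: ill-defined
#' cause out of total deaths; undetermined intent out of injury deaths;
#' unspecified unintentional injury out of unintentional injury deaths;
#' unspecified transport crash out of transport deaths; unspecified road
#' traffic out of road traffic deaths. By default the denominator includes
#' the garbage codes of its own level (the natural reading of "percentage of
#' deaths at that level that are nonspecific"). A zero denominator yields a
#' missing proportion, never 0.
#'
#' @param table A mortality table.
#' @param registry An `rt_registry`.
#' @param include_garbage_in_denominator Include the level's own garbage
#'   deaths in its denominator (default `TRUE`).
#' @return Tibble `country, year, category, garbage_deaths,
#'   denominator_deaths, proportion` (percent, `NA` when undefined).
#' @export
nonspecific_proportions <- function(table, registry = default_registry(),
                                    include_garbage_in_denominator = TRUE) {
  table <- mortality_table(table)
  table$category <- icd_classify(table$cause, registry)
  keys <- table |> distinct(.data$country, .data$year)
  purrr::map(GARBAGE_CATEGORIES, function(cat) {
    in_den <- in_denominator(table$cause, cat, registry)
    if (!include_garbage_in_denominator) {
      in_den <- in_den & table$category != cat
    }
    den <- table[in_den, ] |>
      group_by(.data$country, .data$year) |>
      summarise(denominator_deaths = sum(.data$deaths), .groups = "drop")
    gar <- table |>
      filter(.data$category == cat) |>
      group_by(.data$country, .data$year) |>
      summarise(garbage_deaths = sum(.data$deaths), .groups = "drop")
    keys |>
      left_join(gar, by = c("country", "year")) |>
      left_join(den, by = c("country", "year")) |>
      mutate(
        category = cat,
        garbage_deaths = tidyr::replace_na(.data$garbage_deaths, 0),
        denominator_deaths = tidyr::replace_na(.data$denominator_deaths, 0),
        proportion = ifelse(.data$denominator_deaths > 0,
                            100 * .data$garbage_deaths / .data$denominator_deaths,
                            NA_real_)
      )
  }) |>
    bind_rows() |>
    mutate(category = factor(.data$category, levels = GARBAGE_CATEGORIES)) |>
    select(all_of(c("country", "year", "category", "garbage_deaths",
                    "denominator_deaths", "proportion"))) |>
    arrange(.data$country, .data$year, .data$category)
}

#' Bin coding-quality percentages
#'
#' Five groups, 0%-20%, 21%-40%, 41%-60%, 61%-80% and 81%-100%: a value at a
#' boundary (20, 40, 60, 80) falls in the lower bin, matching the printed
#' interval labels.
#'
#' @param proportion Numeric vector of percentages in `[0, 100]` (`NA`
#'   allowed).
#' @return Factor with levels `P0_20 ... P81_100`.
#' @export
#' @examples
#' bin_proportions(c(20, 20.5, 100))
bin_proportions <- function(proportion) {
  ok <- is.na(proportion) | (proportion >= 0 & proportion <= 100)
  if (!all(ok)) {
    abort(paste0("Proportion(s) outside [0, 100]: ",
                 paste(utils::head(proportion[!ok], 5), collapse = ", ")))
  }
  cut(proportion, breaks = c(-0.001, 20, 40, 60, 80, 100),
      labels = QUALITY_BINS)
}

#' One-stop coding-quality report
#'
#' [nonspecific_proportions()] plus the binned grouping, as one tidy tibble.
#'
#' @inheritParams nonspecific_proportions
#' @return The proportions tibble with an additional `bin` factor column.
#' @export
assess_quality <- function(table, registry = default_registry(),
                           include_garbage_in_denominator = TRUE) {
  nonspecific_proportions(table, registry, include_garbage_in_denominator) |>
    mutate(bin = bin_proportions(.data$proportion))
}

#' Average number of countries per year above a quality threshold
#'
#' Flags each (country, year, category) whose nonspecific proportion exceeds
#' the threshold, then averages the count of flagged countries over reported
#' years — the "countries and territories per year reporting over X%
#' nonspecific mortalities" summary.
#'
#' @param quality Output of [assess_quality()] or
#'   [nonspecific_proportions()].
#' @param threshold Percent threshold (default 20).
#' @return Tibble `category, mean_countries_over_threshold`.
#' @export
summarise_over_threshold <- function(quality, threshold = 20) {
  quality |>
    filter(!is.na(.data$proportion)) |>
    group_by(.data$category, .data$year) |>
    summarise(n_over = sum(.data$proportion > threshold), .groups = "drop") |>
    group_by(.data$category) |>
    summarise(mean_countries_over_threshold = mean(.data$n_over),
              .groups = "drop")
}
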