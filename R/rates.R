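# Age-standardized mortality rates, before and after garbage-code correction.

RATE_SCOPES <- c("overall_rt", "pedestrian", "pedal_cyclist", "motorcyclist",
                 "occupant")

#' Direct age standardization
#'
#' The standard-population-weighted sum of age-specific rates, per 100 000:
#' `rate = 1e5 * sum_a w_a * deaths_a / population_a`. Bands absent from
#' `deaths_by_age` contribute 0; deaths in a band with no (or zero)
#' population are an error naming the band.
#'
#' @param deaths_by_age Tibble `age_group, deaths`.
#' @param population_by_age Tibble `age_group, population`.
#' @param standard A standard population from [load_standard_population()].
#' @return Age-standardized rate per 100 000 standard population.
#' @export
#' @examples
#' std <- load_standard_population()
#' age_standardize(
#'   tibble::tibble(age_group = "0-4", deaths = 10),
#'   tibble::tibble(age_group = "0-4", population = 1e5),
#'   std
#' )
age_standardize <- function(deaths_by_age, population_by_age, standard) {
  joined <- standard |>
    left_join(deaths_by_age, by = "age_group") |>
    left_join(population_by_age, by = "age_group") |>
    mutate(deaths = tidyr::replace_na(.data$deaths, 0))
  bad <- joined$deaths > 0 &
    (is.na(joined$population) | joined$population <= 0)
  if (any(bad)) {
    abort(paste0("Deaths in age band(s) with no population: ",
                 paste(joined$age_group[bad], collapse = ", ")))
  }
  rate_terms <- ifelse(joined$deaths > 0,
                       joined$weight * joined$deaths / joined$population, 0)
  1e5 * sum(rate_terms)
}

# Per-country-year standardized rate for a subset of causes, both sexes
# combined. `table` may contain UNKNOWN-age rows; they are spread first.
scope_rates <- function(table, keep, population, standard, value_name) {
  sub <- table[keep, , drop = FALSE]
  if (any(sub$age_group == "UNKNOWN")) sub <- redistribute_unknown_age(sub)
  deaths <- sub |>
    group_by(.data$country, .data$year, .data$age_group) |>
    summarise(deaths = sum(.data$deaths), .groups = "drop")
  pop <- population |>
    group_by(.data$country, .data$year, .data$age_group) |>
    summarise(population = sum(.data$population), .groups = "drop")
  keys <- table |> distinct(.data$country, .data$year)
  res <- purrr::pmap(keys, function(country, year) {
    d <- deaths[deaths$country == country & deaths$year == year,
                c("age_group", "deaths")]
    p <- pop[pop$country == country & pop$year == year,
             c("age_group", "population")]
    if (nrow(p) == 0) return(NULL)
    tibble(country = country, year = year,
           rate = age_standardize(d, p, standard))
  })
  dropped <- purrr::map_lgl(res, is.null)
  if (any(dropped)) {
    warn(paste0(sum(dropped),
                " country-year(s) without population omitted from rates."))
  }
  out <- bind_rows(res)
  names(out)[names(out) == "rate"] <- value_name
  out
}

scope_filter <- function(codes, scope, registry) {
  switch(scope,
    overall_rt = icd_is_road_traffic(codes, registry),
    pedestrian = icd_road_user(codes, registry, strict = FALSE) %in% "PEDESTRIAN",
    pedal_cyclist = icd_road_user(codes, registry, strict = FALSE) %in% "PEDAL_CYCLIST",
    motorcyclist = icd_road_user(codes, registry, strict = FALSE) %in% "MOTORCYCLIST",
    occupant = icd_road_user(codes, registry, strict = FALSE) %in% "OCCUPANT",
    abort(paste0("Unknown scope: ", scope))
  )
}

#' Corrected and uncorrected age-standardized road traffic rates
#'
#' Computes, per country-year, the age-standardized mortality rate for
#' overall road traffic deaths and for each road-user group, before and
#' after garbage-code correction, plus the corrected/uncorrected ratio.
#' Overall, pedestrian and pedal-cyclist rates use the levels-1-4 corrected
#' table (the unspecified-road-traffic category left in place, since it only
#' moves mass within road traffic); occupant and motorcyclist rates use the
#' levels-1-5 corrected table. Uncorrected rates use the raw table (overall
#' road traffic includes the unspecified-road-traffic codes, which are road
#' traffic deaths of unknown user; user groups count specific codes only).
#' Both sexes are combined.
#'
#' @param uncorrected Raw mortality table.
#' @param corrected_l4 [redistribute()] result with `include_level5 = FALSE`
#'   (or its `$table`).
#' @param corrected_l5 [redistribute()] result with `include_level5 = TRUE`
#'   (or its `$table`).
#' @param population A population table.
#' @param standard A standard population.
#' @param registry An `rt_registry`.
#' @return Tibble `country, year, scope, uncorrected_rate, corrected_rate,
#'   ratio, pct_change` (rates per 100 000; `pct_change = 100 * (ratio - 1)`).
#' @export
user_specific_rates <- function(uncorrected, corrected_l4, corrected_l5,
                                population, standard = load_standard_population(),
                                registry = default_registry()) {
  grab <- function(x) if (inherits(x, "rt_redistribution")) x$table else mortality_table(x)
  uncorrected <- mortality_table(uncorrected)
  l4 <- grab(corrected_l4)
  l5 <- grab(corrected_l5)
  purrr::map(RATE_SCOPES, function(scope) {
    corrected <- if (scope %in% c("occupant", "motorcyclist")) l5 else l4
    unc <- scope_rates(uncorrected,
                       scope_filter(uncorrected$cause, scope, registry),
                       population, standard, "uncorrected_rate")
    cor <- scope_rates(corrected,
                       scope_filter(corrected$cause, scope, registry),
                       population, standard, "corrected_rate")
    inner_join(unc, cor, by = c("country", "year")) |>
      mutate(scope = scope)
  }) |>
    bind_rows() |>
    mutate(
      scope = factor(.data$scope, levels = RATE_SCOPES),
      ratio = ifelse(.data$uncorrected_rate > 0,
                     .data$corrected_rate / .data$uncorrected_rate, NA_real_),
      pct_change = 100 * (.data$ratio - 1)
    ) |>
    select(all_of(c("country", "year", "scope", "uncorrected_rate",
                    "corrected_rate", "ratio", "pct_change"))) |>
    arrange(.data$country, .data$year, .data$scope)
}
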