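# Fixtures built in code: tiny hand-sized tables and small simulated panels.

# Quick long-table constructor; defaults collapse to a single stratum.
mt <- function(cause, deaths, country = "AAA", year = 2017L, sex = "male",
               age_group = "30-34") {
  mortality_table(tibble::tibble(
    country = country, year = year, sex = sex, age_group = age_group,
    cause = cause, deaths = deaths
  ))
}

# Per-country-year totals, as a named-key data frame for joins in tests.
totals_by_cy <- function(table) {
  dplyr::summarise(dplyr::group_by(table, country, year),
                   deaths = sum(deaths), .groups = "drop")
}

# Max absolute per-cell difference between two mortality tables.
max_cell_gap <- function(a, b) {
  m <- dplyr::full_join(
    a, b, by = c("country", "year", "sex", "age_group", "cause"),
    suffix = c("_a", "_b")
  )
  m$deaths_a[is.na(m$deaths_a)] <- 0
  m$deaths_b[is.na(m$deaths_b)] <- 0
  max(abs(m$deaths_a - m$deaths_b))
}

# Overall road-traffic age-standardized rate per country-year.
overall_rt_rates <- function(table, population,
                             standard = load_standard_population()) {
  rt <- table[icd_is_road_traffic(table$cause), , drop = FALSE]
  deaths <- dplyr::summarise(
    dplyr::group_by(rt, country, year, age_group),
    deaths = sum(deaths), .groups = "drop")
  pop <- dplyr::summarise(
    dplyr::group_by(population, country, year, age_group),
    population = sum(population), .groups = "drop")
  keys <- dplyr::distinct(deaths, country, year)
  purrr::pmap_dfr(keys, function(country, year) {
    tibble::tibble(
      country = country, year = year,
      rate = age_standardize(
        deaths[deaths$country == country & deaths$year == year,
               c("age_group", "deaths")],
        pop[pop$country == country & pop$year == year,
            c("age_group", "population")],
        standard
      )
    )
  })
}

same_year_rule <- window_rule(half_widths = c(0L, 0L, 0L, 0L))
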