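# Proportionate redistribution of garbage-coded deaths with adaptive
# temporal windows, cascading top-down through the five-level hierarchy
# (all causes > injuries > unintentional injuries > transport > road traffic).

#' Temporal window rule
#'
#' Maps a country-year's nonspecific proportion to the span of years pooled
#' when building its redistribution weights: below 30% the study year alone;
#' 30%-49% a three-year window; 50%-69% a five-year window; 70% and above a
#' seven-year window. A proportion exactly at a threshold takes the wider
#' window.
#'
#' @param thresholds Increasing breakpoints on the garbage proportion
#'   (fractions of 1).
#' @param half_widths Window half-widths (years either side of the study
#'   year), one more than `thresholds`, non-decreasing.
#' @return An `rt_window_rule`.
#' @export
window_rule <- function(thresholds = c(0.30, 0.50, 0.70),
                        half_widths = c(0L, 1L, 2L, 3L)) {
  if (length(half_widths) != length(thresholds) + 1) {
    abort("Need one more half-width than thresholds.")
  }
  if (is.unsorted(thresholds, strictly = TRUE) || is.unsorted(half_widths)) {
    abort("Thresholds must increase and half-widths must not decrease.")
  }
  structure(list(thresholds = thresholds,
                 half_widths = as.integer(half_widths)),
            class = "rt_window_rule")
}

#' Select the temporal window for one country-year
#'
#' Applies the window rule, then availability: if every nominal window year
#' is present in `available_years` the nominal window is used; if any is
#' missing, all available years are used instead (the all-available-data
#' fallback).
#'
#' @param proportion The category's garbage proportion, a fraction in
#'   `[0, 1]`.
#' @param year The study year.
#' @param available_years Years with data for the country.
#' @param rule An [window_rule()].
#' @return Sorted integer vector of years.
#' @export
#' @examples
#' select_window(0.45, 2017, 2015:2020) # three-year window
#' select_window(0.72, 2016, c(2015, 2016, 2018)) # fallback: all available
select_window <- function(proportion, year, available_years,
                          rule = window_rule()) {
  if (length(available_years) == 0) abort("available_years is empty.")
  if (is.na(proportion) || proportion < 0 || proportion > 1) {
    abort("proportion must be a fraction in [0, 1].")
  }
  available_years <- sort(unique(as.integer(available_years)))
  h <- rule$half_widths[findInterval(proportion, rule$thresholds) + 1L]
  nominal <- (year - h):(year + h)
  if (all(nominal %in% available_years)) nominal else available_years
}

empty_provenance <- function() {
  tibble(country = character(), year = integer(), sex = character(),
         age_group = character(), cause = character(), category = character(),
         added = double())
}

empty_unallocated <- function() {
  tibble(country = character(), year = integer(), category = character(),
         mass = double())
}

# One cascade step: redistribute a single garbage category, returning the
# updated table plus the provenance and unallocated ledgers for the step.
redistribute_category <- function(table, category,
                                  registry = default_registry(),
                                  rule = window_rule(),
                                  strata = c("age_sex", "none")) {
  strata <- match.arg(strata)
  table <- mortality_table(table)
  is_cat <- icd_classify(table$cause, registry) == category
  garbage <- table[is_cat, , drop = FALSE]
  rest <- table[!is_cat, , drop = FALSE]
  if (nrow(garbage) == 0) {
    return(list(table = table, provenance = empty_provenance(),
                unallocated = empty_unallocated()))
  }

  # windowing proportion: the category's garbage share of its own
  # hierarchy-level denominator, per country-year
  denom <- table[in_denominator(table$cause, category, registry), ] |>
    group_by(.data$country, .data$year) |>
    summarise(denom = sum(.data$deaths), .groups = "drop")
  props <- garbage |>
    group_by(.data$country, .data$year) |>
    summarise(g = sum(.data$deaths), .groups = "drop") |>
    left_join(denom, by = c("country", "year")) |>
    mutate(p = ifelse(.data$denom > 0, pmin(.data$g / .data$denom, 1), 1))

  avail_by_country <- table |> distinct(.data$country, .data$year)
  window_map <- purrr::pmap(props, function(country, year, g, denom, p) {
    yrs <- avail_by_country$year[avail_by_country$country == country]
    tibble(country = country, year = year,
           wyear = select_window(p, year, yrs, rule))
  }) |> bind_rows()

  # pooled target-set weights over each country-year's window
  targets <- table[in_target(table$cause, category, registry), , drop = FALSE]
  pool <- window_map |>
    inner_join(targets, by = c("country", "wyear" = "year"),
               relationship = "many-to-many") |>
    group_by(.data$country, .data$year, .data$sex, .data$age_group,
             .data$cause) |>
    summarise(w = sum(.data$deaths), .groups = "drop")
  pool_age <- pool |>
    group_by(.data$country, .data$year, .data$age_group, .data$cause) |>
    summarise(w = sum(.data$w), .groups = "drop")
  pool_all <- pool |>
    group_by(.data$country, .data$year, .data$cause) |>
    summarise(w = sum(.data$w), .groups = "drop")

  g_strata <- garbage |>
    group_by(.data$country, .data$year, .data$sex, .data$age_group) |>
    summarise(g = sum(.data$deaths), .groups = "drop")

  allocate <- function(g_df, pool_df, by_cols) {
    joined <- g_df |>
      inner_join(pool_df, by = by_cols, relationship = "many-to-many") |>
      group_by(.data$country, .data$year, .data$sex, .data$age_group) |>
      mutate(added = .data$g * .data$w / sum(.data$w)) |>
      ungroup() |>
      filter(is.finite(.data$added), .data$added > 0)
    placed_keys <- joined |>
      distinct(.data$country, .data$year, .data$sex, .data$age_group)
    list(
      alloc = joined |> select(all_of(c("country", "year", "sex", "age_group",
                                        "cause", "added"))),
      remaining = g_df |>
        anti_join(placed_keys, by = c("country", "year", "sex", "age_group"))
    )
  }

  if (strata == "none") {
    step1 <- allocate(g_strata, pool_all, c("country", "year"))
    parts <- list(step1$alloc)
    remaining <- step1$remaining
  } else {
    # fallback ladder: own (sex, age) stratum -> sexes pooled within age ->
    # whole country-year pool
    step1 <- allocate(g_strata, pool, c("country", "year", "sex", "age_group"))
    step2 <- allocate(step1$remaining, pool_age,
                      c("country", "year", "age_group"))
    step3 <- allocate(step2$remaining, pool_all, c("country", "year"))
    parts <- list(step1$alloc, step2$alloc, step3$alloc)
    remaining <- step3$remaining
  }
  provenance <- bind_rows(parts) |> mutate(category = category)
  unallocated <- remaining |>
    group_by(.data$country, .data$year) |>
    summarise(mass = sum(.data$g), .groups = "drop") |>
    mutate(category = category) |>
    select(all_of(c("country", "year", "category", "mass")))
  if (nrow(unallocated) > 0) {
    warn(paste0(category, ": ", round(sum(unallocated$mass), 3),
                " death(s) with empty target pool left unallocated in ",
                nrow(unallocated), " stratum/strata."))
  }

  out <- bind_rows(
    rest,
    provenance |>
      select(all_of(c("country", "year", "sex", "age_group", "cause"))) |>
      mutate(deaths = provenance$added)
  ) |>
    group_by(.data$country, .data$year, .data$sex, .data$age_group,
             .data$cause) |>
    summarise(deaths = sum(.data$deaths), .groups = "drop")
  list(table = mortality_table(out), provenance = provenance,
       unallocated = unallocated)
}

#' Redistribute nonspecific deaths through the five-level cascade
#'
#' Applies proportionate redistribution category by category, top-down the
#' hierarchy: ill-defined causes, then undetermined intent, then unspecified
#' unintentional injury, then unspecified transport, and finally (when
#' `include_level5 = TRUE`) unspecified road traffic. After each step the
#' redistributed mass is merged into the table before the next step's
#' proportions and target pools are computed, and the processed category's
#' garbage rows are removed (their mass lives on in specific causes or in the
#' unallocated ledger).
#'
#' For each country-year, a category's garbage deaths are allocated within
#' (sex, age band) strata proportionally to the specific deaths of the
#' category's target set, pooled over the temporal window chosen by
#' [select_window()] from the category's garbage proportion. A stratum with
#' an empty target pool falls back to sexes pooled within the age band, then
#' to the whole country-year pool, and finally to the unallocated ledger.
#' Level-5 targets are occupant and motorcyclist codes only, reflecting that
#' unspecified road traffic codes predominantly hide those two road-user
#' groups.
#'
#' The first four levels are used for overall road traffic mortality and for
#' pedestrian/pedal-cyclist rates; all five for occupant and motorcyclist
#' rates — pass `include_level5` accordingly, or use both variants as
#' [user_specific_rates()] does.
#'
#' @param table A mortality table.
#' @param registry An `rt_registry`.
#' @param include_level5 Redistribute the unspecified-road-traffic category
#'   too (default `TRUE`).
#' @param rule An [window_rule()].
#' @param strata `"age_sex"` (default) redistributes within (sex, age band)
#'   strata; `"none"` uses the country-year cause distribution for every
#'   stratum.
#' @return An `rt_redistribution`: list with `table` (corrected mortality
#'   tibble, fractional counts), `provenance` (per-cell added mass by source
#'   category), `unallocated` (garbage mass with no feasible target), and the
#'   call settings. `tidy()` returns the provenance ledger, `glance()` the
#'   conservation summary.
#' @export
redistribute <- function(table, registry = default_registry(),
                         include_level5 = TRUE, rule = window_rule(),
                         strata = c("age_sex", "none")) {
  strata <- match.arg(strata)
  table <- mortality_table(table)
  cats <- GARBAGE_CATEGORIES
  if (!include_level5) cats <- setdiff(cats, "UNSPEC_RT")
  provenance <- list()
  unallocated <- list()
  current <- table
  for (cat in cats) {
    step <- redistribute_category(current, cat, registry, rule, strata)
    current <- step$table
    provenance[[cat]] <- step$provenance
    unallocated[[cat]] <- step$unallocated
  }
  structure(
    list(
      table = current,
      provenance = bind_rows(provenance) %||% empty_provenance(),
      unallocated = bind_rows(unallocated) %||% empty_unallocated(),
      input_total = sum(table$deaths),
      include_level5 = include_level5,
      strata = strata,
      rule = rule
    ),
    class = "rt_redistribution"
  )
}

#' @export
print.rt_redistribution <- function(x, ...) {
  cat("<rt_redistribution>",
      if (x$include_level5) "levels 1-5" else "levels 1-4",
      "| strata:", x$strata, "\n")
  cat("  input deaths:     ", format(x$input_total), "\n")
  cat("  output deaths:    ", format(sum(x$table$deaths)), "\n")
  cat("  redistributed:    ", format(sum(x$provenance$added)), "\n")
  cat("  unallocated:      ", format(sum(x$unallocated$mass)), "\n")
  invisible(x)
}

#' @rdname redistribute
#' @param x,... An `rt_redistribution` and unused arguments.
#' @export
tidy.rt_redistribution <- function(x, ...) {
  as_tibble(x$provenance)
}

#' @rdname redistribute
#' @export
glance.rt_redistribution <- function(x, ...) {
  tibble(
    input_deaths = x$input_total,
    output_deaths = sum(x$table$deaths),
    redistributed = sum(x$provenance$added),
    unallocated = sum(x$unallocated$mass),
    include_level5 = x$include_level5,
    strata = x$strata
  )
}
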