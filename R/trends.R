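# Geometric-mean average annual change, projection to 2021/2030 and on-track
# classification against the 50%-reduction road safety target.

#' Road traffic death series
#'
#' Sums road traffic deaths (V01-V89, unspecified-user codes included) per
#' country-year — the series fed to [annual_change()].
#'
#' @param table A mortality table (raw or corrected).
#' @param registry An `rt_registry`.
#' @return Tibble `country, year, deaths`.
#' @export
rt_death_series <- function(table, registry = default_registry()) {
  table <- mortality_table(table)
  table[icd_is_road_traffic(table$cause, registry), , drop = FALSE] |>
    group_by(.data$country, .data$year) |>
    summarise(deaths = sum(.data$deaths), .groups = "drop")
}

#' Geometric-mean average annual change of one series
#'
#' The constant multiplicative yearly rate carrying the first observed count
#' to the last over the observed span:
#' `r = (D_last / D_first)^(1 / (last_year - first_year)) - 1`. This is the
#' geometric mean of the year-over-year ratios when years are consecutive
#' and annualizes over the endpoint span when there are gaps, making it
#' robust to intermediate extremes. A series ending at zero deaths gives
#' `r = -1` (a -100% annual change); a series with fewer than two years, or
#' zero deaths in its first year, has no defined trend.
#'
#' @param years Integer years (need not be consecutive).
#' @param deaths Death counts, same length.
#' @return One-row tibble `r, first_year, last_year, n_years_used,
#'   first_deaths, last_deaths`.
#' @export
#' @examples
#' geometric_change(c(2015, 2017), c(100, 81)) # r = -0.10
geometric_change <- function(years, deaths) {
  if (length(years) != length(deaths)) abort("years/deaths length mismatch.")
  o <- order(years)
  years <- as.integer(years[o])
  deaths <- as.double(deaths[o])
  if (length(years) < 2) abort("Trend undefined: fewer than two years.")
  if (anyDuplicated(years)) abort("Duplicate years in series.")
  d_first <- deaths[1]
  d_last <- deaths[length(deaths)]
  if (d_first <= 0) abort("Trend undefined: zero deaths in first year.")
  span <- years[length(years)] - years[1]
  r <- if (d_last == 0) -1 else (d_last / d_first)^(1 / span) - 1
  tibble(r = r, first_year = years[1], last_year = years[length(years)],
         n_years_used = length(years), first_deaths = d_first,
         last_deaths = d_last)
}

#' Average annual change per country
#'
#' Applies [geometric_change()] to each country's road traffic death series.
#' Countries with fewer than two observed years, or no deaths in their first
#' observed year, are returned with `r = NA` and flagged in a warning.
#'
#' @param series Tibble `country, year, deaths` (see [rt_death_series()]).
#' @param year_range Optional year filter applied before estimation.
#' @return Tibble `country, r, first_year, last_year, n_years_used,
#'   first_deaths, last_deaths`.
#' @export
annual_change <- function(series, year_range = NULL) {
  if (!is.null(year_range)) series <- series |> filter(.data$year %in% year_range)
  out <- series |>
    group_by(.data$country) |>
    dplyr::group_modify(function(d, key) {
      tryCatch(geometric_change(d$year, d$deaths),
               error = function(e) tibble(
                 r = NA_real_, first_year = min(d$year), last_year = max(d$year),
                 n_years_used = nrow(d), first_deaths = d$deaths[which.min(d$year)],
                 last_deaths = d$deaths[which.max(d$year)]
               ))
    }) |>
    ungroup()
  if (anyNA(out$r)) {
    warn(paste0("No defined trend for: ",
                paste(out$country[is.na(out$r)], collapse = ", ")))
  }
  out
}

#' Project road traffic deaths to 2021 and 2030
#'
#' Chains the geometric annual change from each country's last observed year:
#' `deaths_Y = last_deaths * (1 + r)^(Y - last_year)`. The projected percent
#' change between 2021 and 2030 is `100 * ((1 + r)^9 - 1)` — independent of
#' the base — evaluated as -100 in the `r = -1` limit. A country is on track
#' for the 50%-reduction target when that percent change is at most -50.
#'
#' @param trends Output of [annual_change()] (rows with `NA` trend are
#'   dropped).
#' @param years Two projection years (default 2021 and 2030).
#' @return Tibble `country, r, deaths_2021, deaths_2030,
#'   pct_change_2021_2030, on_track`.
#' @export
project_trend <- function(trends, years = c(2021L, 2030L)) {
  trends <- trends |> filter(!is.na(.data$r))
  horizon <- diff(sort(years))
  out <- trends |>
    mutate(
      d1 = .data$last_deaths * (1 + .data$r)^(years[1] - .data$last_year),
      d2 = .data$last_deaths * (1 + .data$r)^(years[2] - .data$last_year),
      pct_change = 100 * ((1 + .data$r)^horizon - 1),
      # tolerance keeps the exact-halving rate on track despite rounding
      on_track = .data$pct_change <= -50 + 1e-9
    )
  names(out)[names(out) == "d1"] <- paste0("deaths_", years[1])
  names(out)[names(out) == "d2"] <- paste0("deaths_", years[2])
  names(out)[names(out) == "pct_change"] <-
    paste0("pct_change_", years[1], "_", years[2])
  out |> select(all_of(c("country", "r",
                         paste0("deaths_", years[1]),
                         paste0("deaths_", years[2]),
                         paste0("pct_change_", years[1], "_", years[2]),
                         "on_track")))
}

#' Classify the shift between uncorrected and corrected trends
#'
#' Per country: `sign_flip_pos` when the corrected annual change rate has a
#' higher sign than the uncorrected one (e.g. a decline turning into growth;
#' zero counts as its own sign), `sign_flip_neg` for the reverse,
#' `shift_gt_10pt` when the rates differ by more than 10 percentage points
#' without a sign change, else `minor`.
#'
#' @param uncorrected,corrected [annual_change()] tibbles on the raw and
#'   corrected series.
#' @return Tibble `country, r_uncorrected, r_corrected, shift`.
#' @export
classify_shift <- function(uncorrected, corrected) {
  joined <- inner_join(
    uncorrected |> select(all_of(c("country", "r"))),
    corrected |> select(all_of(c("country", "r"))),
    by = "country", suffix = c("_uncorrected", "_corrected")
  ) |> filter(!is.na(.data$r_uncorrected), !is.na(.data$r_corrected))
  joined |>
    mutate(shift = dplyr::case_when(
      sign(.data$r_corrected) > sign(.data$r_uncorrected) ~ "sign_flip_pos",
      sign(.data$r_corrected) < sign(.data$r_uncorrected) ~ "sign_flip_neg",
      abs(100 * (.data$r_corrected - .data$r_uncorrected)) > 10 ~ "shift_gt_10pt",
      .default = "minor"
    ))
}
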