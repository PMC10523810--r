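# Synthetic civil-registration-style mortality panels with known ground truth.
#
# The simulator emulates the structure of a national vital-registration
# extract: country-year panels of ICD-10-coded death counts by sex and
# five-year age band, with a configurable true cause distribution, a
# multiplicative annual drift on road traffic deaths, and controllable
# injection of nonspecific ("garbage") codes in each of the five categories.

# Representative garbage code used by the deterministic injector.
GARBAGE_REPRESENTATIVE <- c(
  ILL_DEFINED = "R99",
  UNDETERMINED_INTENT = "Y34",
  UNSPEC_UNINTENTIONAL = "X59",
  UNSPEC_TRANSPORT = "V99",
  UNSPEC_RT = "V89.2"
)

#' Default true cause mix for simulated panels
#'
#' Roughly forty specific ICD-10 codes spanning every level of the
#' redistribution hierarchy — non-injury causes, intentional injuries,
#' unintentional non-transport injuries, non-road transport, and all road-user
#' groups — so every redistribution step has a non-empty target pool. Road
#' traffic deaths are about 2% of the total, injuries about 5%, in line with
#' typical national cause-of-death profiles.
#'
#' @return Named numeric vector of probabilities summing to 1.
#' @export
default_cause_mix <- function() {
  mix <- c(
    # non-injury
    A16.2 = 0.010, B24 = 0.008, C34.9 = 0.090, C50.9 = 0.040, C61 = 0.030,
    E11.9 = 0.050, E86 = 0.010, G30.9 = 0.040, I21.9 = 0.130, I64 = 0.110,
    I50.9 = 0.060, J18.9 = 0.080, J44.9 = 0.070, K70.3 = 0.020, N18.9 = 0.030,
    A41.9 = 0.040, C18.9 = 0.030, I25.1 = 0.100,
    # intentional injury (X60-Y09)
    X70.0 = 0.004, X74.9 = 0.002, X95.9 = 0.002, Y04.0 = 0.001,
    # unintentional non-transport injury (W00-X59 block)
    W01.0 = 0.006, W13.9 = 0.002, W65 = 0.002, W78 = 0.002,
    X00.0 = 0.002, X42.9 = 0.004,
    # transport, non-road (V90-V98)
    V90.2 = 0.001, V95.9 = 0.001,
    # road traffic: pedestrians
    V02.1 = 0.002, V03.1 = 0.002, V09.2 = 0.001,
    # pedal cyclists
    V12.4 = 0.001, V13.3 = 0.001,
    # motorcyclists
    V22.4 = 0.002, V23.3 = 0.002, V29.4 = 0.002,
    # vehicle occupants
    V43.5 = 0.003, V47.5 = 0.002, V49.4 = 0.002, V53.6 = 0.001,
    # other road traffic
    V80.1 = 0.001, V82.1 = 0.001
  )
  mix / sum(mix)
}

default_age_sex_structure <- function() {
  age_p <- c(0.030, 0.010, 0.010, 0.020, 0.030, 0.030, 0.030, 0.035, 0.040,
             0.050, 0.060, 0.070, 0.085, 0.095, 0.105, 0.115, 0.105, 0.080)
  tidyr::expand_grid(sex = c("male", "female"), age_group = AGE_BANDS) |>
    mutate(prob = rep(age_p, times = 2) * ifelse(.data$sex == "male", 0.55, 0.45))
}

default_population_structure <- function() {
  age_p <- c(0.08, 0.08, 0.08, 0.08, 0.08, 0.08, 0.07, 0.07, 0.06, 0.06,
             0.05, 0.05, 0.04, 0.04, 0.03, 0.02, 0.02, 0.01)
  tidyr::expand_grid(sex = c("male", "female"), age_group = AGE_BANDS) |>
    mutate(prob = rep(age_p, times = 2) * 0.5)
}

#' Simulation configuration
#'
#' @param n_countries Number of simulated countries (`C01`, `C02`, ...).
#' @param years Vector of calendar years in the panel.
#' @param true_cause_mix Named probability vector over specific (non-garbage)
#'   ICD-10 codes; normalized to sum to 1.
#' @param age_sex_structure Tibble `sex, age_group, prob` for the death
#'   distribution across strata; normalized.
#' @param total_deaths Deaths per country-year in the first year: a single
#'   number or a per-country named vector.
#' @param garbage_fractions Named vector (category -> fraction in `[0, 1)`)
#'   of each category's eligible deaths relabelled to a nonspecific code.
#' @param annual_change Multiplicative annual drift on road traffic deaths: a
#'   single signed fraction or a per-country named vector (e.g. `-0.05` for a
#'   5% yearly decline).
#' @param injection_mode `"proportional"` (every eligible cell loses the same
#'   fraction) or `"biased"` (relabelling propensity proportional to
#'   `bias_weights`, to probe the proportionate method's core assumption).
#' @param bias_weights Named relative propensity per cause (biased mode).
#' @param sampling `"deterministic"` (expected fractional counts; the exact
#'   inverse of the redistribution cascade) or `"stochastic"` (integer
#'   multinomial truth and binomial relabelling).
#' @param population_base Person-years per country-year.
#' @param seed RNG seed used by stochastic sampling.
#' @return A validated `rt_sim_config` list.
#' @export
sim_config <- function(n_countries = 20,
                       years = 2015:2020,
                       true_cause_mix = default_cause_mix(),
                       age_sex_structure = default_age_sex_structure(),
                       total_deaths = 10000,
                       garbage_fractions = c(ILL_DEFINED = 0, UNDETERMINED_INTENT = 0,
                                             UNSPEC_UNINTENTIONAL = 0,
                                             UNSPEC_TRANSPORT = 0, UNSPEC_RT = 0),
                       annual_change = 0,
                       injection_mode = c("proportional", "biased"),
                       bias_weights = NULL,
                       sampling = c("deterministic", "stochastic"),
                       population_base = 1e6,
                       seed = 1L) {
  injection_mode <- match.arg(injection_mode)
  sampling <- match.arg(sampling)
  icd_validate(names(true_cause_mix))
  if (any(true_cause_mix < 0)) abort("Cause mix probabilities must be >= 0.")
  garbage_in_mix <- icd_classify(names(true_cause_mix)) != "NONE"
  if (any(garbage_in_mix)) {
    abort(paste0("true_cause_mix contains nonspecific code(s): ",
                 paste(names(true_cause_mix)[garbage_in_mix], collapse = ", ")))
  }
  true_cause_mix <- true_cause_mix / sum(true_cause_mix)
  gf <- stats::setNames(rep(0, length(GARBAGE_CATEGORIES)), GARBAGE_CATEGORIES)
  gf[names(garbage_fractions)] <- garbage_fractions
  if (any(gf < 0 | gf >= 1)) abort("Garbage fractions must be in [0, 1).")
  if (injection_mode == "biased" && is.null(bias_weights)) {
    abort("Biased injection needs bias_weights.")
  }
  structure(
    list(
      n_countries = as.integer(n_countries), years = sort(as.integer(years)),
      true_cause_mix = true_cause_mix,
      age_sex_structure = age_sex_structure |>
        mutate(prob = .data$prob / sum(.data$prob)),
      total_deaths = total_deaths, garbage_fractions = gf,
      annual_change = annual_change, injection_mode = injection_mode,
      bias_weights = bias_weights, sampling = sampling,
      population_base = population_base, seed = as.integer(seed)
    ),
    class = "rt_sim_config"
  )
}

#' Simulate a vital-registration panel with known ground truth
#'
#' Draws a truth table of specific-cause deaths from the configured cause mix
#' and age-sex structure (deterministically as expected counts, or
#' multinomially), applies the configured road-traffic drift, generates a
#' matching population table, and produces the observed table by injecting
#' garbage codes with [inject_garbage()]. Per (country, year), observed and
#' truth totals are identical: injection relabels deaths, never creates them.
#'
#' @param config An [sim_config()] object.
#' @param registry An `rt_registry`.
#' @return An `rt_panel` list with elements `observed`, `truth` (both
#'   mortality tibbles) and `population`.
#' @export
simulate_panel <- function(config, registry = default_registry()) {
  stopifnot(inherits(config, "rt_sim_config"))
  set.seed(config$seed)
  countries <- sprintf("C%02d", seq_len(config$n_countries))
  totals <- config$total_deaths
  if (length(totals) == 1 && is.null(names(totals))) {
    totals <- stats::setNames(rep(totals, length(countries)), countries)
  }
  drift <- config$annual_change
  if (length(drift) == 1 && is.null(names(drift))) {
    drift <- stats::setNames(rep(drift, length(countries)), countries)
  }
  is_rt <- icd_is_road_traffic(names(config$true_cause_mix), registry)

  cells <- tidyr::expand_grid(
    country = countries, year = config$years,
    config$age_sex_structure,
    tibble(cause = names(config$true_cause_mix),
           mix = unname(config$true_cause_mix), rt = is_rt)
  )
  y0 <- min(config$years)
  cells <- cells |>
    mutate(mu = totals[.data$country] * .data$prob * .data$mix *
             ifelse(.data$rt,
                    (1 + drift[.data$country])^(.data$year - y0), 1))

  if (config$sampling == "deterministic") {
    cells$deaths <- cells$mu
  } else {
    cells <- cells |>
      group_by(.data$country, .data$year) |>
      mutate(deaths = as.double(stats::rmultinom(
        1, size = round(sum(.data$mu)), prob = .data$mu
      )[, 1])) |>
      ungroup()
  }
  truth <- mortality_table(
    cells |> filter(.data$deaths > 0) |>
      select(all_of(c("country", "year", "sex", "age_group", "cause", "deaths")))
  )
  population <- tidyr::expand_grid(
    country = countries, year = config$years, default_population_structure()
  ) |>
    mutate(population = config$population_base * .data$prob) |>
    select(all_of(c("country", "year", "sex", "age_group", "population"))) |>
    population_table()

  observed <- inject_garbage(truth, config, registry)
  structure(list(observed = observed, truth = truth, population = population,
                 config = config),
            class = "rt_panel")
}

#' Inject nonspecific (garbage) codes into a truth table
#'
#' For each garbage category with fraction `f`, relabels mass from the
#' category's eligible cells (deaths whose cause lies in the category's
#' denominator and target set) to a nonspecific code of that category,
#' conserving totals per (country, year, sex, age band). Categories are
#' applied bottom-up the hierarchy (unspecified road traffic first,
#' ill-defined last), the mirror image of the top-down redistribution
#' cascade, so that deterministic proportional injection is exactly inverted
#' by redistribution with same-year windows.
#'
#' In `"proportional"` mode every eligible cell loses the same fraction `f`;
#' in `"biased"` mode a cell's relabelling propensity is scaled by its
#' cause's `bias_weights` entry (eligible-death-weighted mean propensity
#' equals `f`, capped at 0.99). Deterministic sampling moves exact fractional
#' mass onto one representative code per category (R99, Y34, X59, V99,
#' V89.2); stochastic sampling relabels `rbinom(deaths, p)` of each integer
#' cell.
#'
#' @param truth Mortality table containing no garbage codes.
#' @param config An [sim_config()].
#' @param registry An `rt_registry`.
#' @return The observed mortality tibble.
#' @export
inject_garbage <- function(truth, config, registry = default_registry()) {
  truth <- mortality_table(truth)
  if (any(icd_classify(truth$cause, registry) != "NONE")) {
    abort("Truth table already contains nonspecific codes.")
  }
  out <- truth
  for (cat in rev(GARBAGE_CATEGORIES)) {
    f <- config$garbage_fractions[[cat]]
    if (f <= 0) next
    specific <- icd_classify(out$cause, registry) == "NONE"
    eligible <- specific & in_denominator(out$cause, cat, registry) &
      in_target(out$cause, cat, registry)
    if (!any(eligible)) {
      warn(paste0("No eligible deaths for category ", cat, "; injection skipped."))
      next
    }
    p <- rep(f, sum(eligible))
    if (config$injection_mode == "biased") {
      w <- config$bias_weights[out$cause[eligible]]
      w[is.na(w)] <- 1
      wbar <- sum(w * out$deaths[eligible]) / sum(out$deaths[eligible])
      p <- pmin(f * w / wbar, 0.99)
    }
    if (config$sampling == "deterministic") {
      moved <- out$deaths[eligible] * p
    } else {
      moved <- stats::rbinom(sum(eligible), round(out$deaths[eligible]), p)
    }
    garbage_rows <- out[eligible, , drop = FALSE] |>
      mutate(cause = GARBAGE_REPRESENTATIVE[[cat]], deaths = moved) |>
      filter(.data$deaths > 0) |>
      group_by(.data$country, .data$year, .data$sex, .data$age_group,
               .data$cause) |>
      summarise(deaths = sum(.data$deaths), .groups = "drop")
    out$deaths[eligible] <- out$deaths[eligible] - moved
    out <- bind_rows(out |> filter(.data$deaths > 0), garbage_rows)
  }
  mortality_table(out)
}

#' @export
print.rt_panel <- function(x, ...) {
  cat("<rt_panel>", x$config$n_countries, "countries,",
      paste(range(x$config$years), collapse = "-"), "\n")
  cat("  observed:", nrow(x$observed), "rows,",
      format(sum(x$observed$deaths), big.mark = ","), "deaths\n")
  cat("  garbage fractions:",
      paste(names(x$config$garbage_fractions),
            x$config$garbage_fractions, sep = "=", collapse = " "), "\n")
  invisible(x)
}

#' @export
glance.rt_panel <- function(x, ...) {
  tibble(
    n_countries = x$config$n_countries,
    n_years = length(x$config$years),
    total_deaths = sum(x$observed$deaths),
    garbage_deaths = sum(x$observed$deaths[
      icd_classify(x$observed$cause) != "NONE"]),
    sampling = x$config$sampling,
    injection_mode = x$config$injection_mode
  )
}
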