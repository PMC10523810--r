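test_that("window widths follow the 30/50/70 thresholds, ties widen", {
  widths <- vapply(c(0.299, 0.30, 0.49, 0.50, 0.69, 0.70), function(p) {
    length(select_window(p, 2017, 2010:2024))
  }, integer(1))
  expect_equal(widths, c(1L, 3L, 3L, 5L, 5L, 7L))
  expect_equal(select_window(0.25, 2017, 2015:2020), 2017L)
  expect_equal(select_window(0.45, 2017, 2015:2020), 2016:2018)
  expect_equal(select_window(0.55, 2017, 2015:2020), 2015:2019)
  expect_equal(select_window(0.95, 2018, 2015:2021), 2015:2021)
})

test_that("any missing nominal year triggers the all-available fallback", {
  expect_equal(select_window(0.72, 2016, c(2015, 2016, 2018)),
               c(2015L, 2016L, 2018L))
  expect_equal(select_window(0.45, 2020, 2015:2020), 2015:2020)
  expect_equal(select_window(0.45, 2019, 2015:2020), 2018:2020)
  expect_error(select_window(0.5, 2017, integer(0)), "empty")
  expect_error(select_window(1.2, 2017, 2015:2020), "\\[0, 1\\]")
})

test_that("windows are monotone in the garbage proportion", {
  years <- 2010:2024
  ps <- seq(0, 1, by = 0.01)
  w <- vapply(ps, function(p) length(select_window(p, 2017, years)), integer(1))
  expect_true(all(diff(w) >= 0))
})

test_that("proportionate split matches hand-computed allocations", {
  # same-year targets {A:60, B:40}, garbage 10 -> +6 / +4
  tab <- dplyr::bind_rows(
    mt("I21.9", 60), mt("C34.9", 40), mt("R99", 10))
  res <- redistribute(tab, rule = same_year_rule)
  out <- res$table
  expect_equal(out$deaths[out$cause == "I21.9"], 66)
  expect_equal(out$deaths[out$cause == "C34.9"], 44)
  expect_false(any(out$cause == "R99"))

  # pooled over a three-year window: targets {A:30, B:10, C:0} -> 7.5 / 2.5
  tab2 <- dplyr::bind_rows(
    mt("I21.9", 10, year = 2016L), mt("C34.9", 4, year = 2016L),
    mt("I21.9", 12, year = 2017L), mt("C34.9", 3, year = 2017L),
    # 40% garbage in 2017 selects the three-year window
    mt("R99", 10, year = 2017L),
    mt("I21.9", 8, year = 2018L), mt("C34.9", 3, year = 2018L),
    mt("J18.9", 0.0001, year = 2017L)
  )
  q <- nonspecific_proportions(tab2)
  p2017 <- q$proportion[q$category == "ILL_DEFINED" & q$year == 2017]
  expect_gt(p2017 / 100, 0.30)
  expect_lt(p2017 / 100, 0.50)
  res2 <- redistribute(tab2)
  out2 <- res2$table
  # pooled weights I21.9: 30, C34.9: 10 (J18.9 negligible)
  expect_equal(out2$deaths[out2$cause == "I21.9" & out2$year == 2017],
               12 + 7.5, tolerance = 1e-3)
  expect_equal(out2$deaths[out2$cause == "C34.9" & out2$year == 2017],
               3 + 2.5, tolerance = 1e-3)
})

test_that("a garbage-free table is a fixpoint", {
  tab <- mortality_table(
    dplyr::bind_rows(mt("I21.9", 60), mt("V43.5", 4), mt("V23.4", 2)))
  res <- redistribute(tab)
  expect_equal(res$table, tab)
  expect_equal(nrow(res$provenance), 0L)
  expect_equal(nrow(res$unallocated), 0L)
})

test_that("deterministic proportional injection is inverted exactly", {
  cfg <- sim_config(
    n_countries = 4, years = 2015:2017, total_deaths = 2000,
    garbage_fractions = c(ILL_DEFINED = 0.15, UNDETERMINED_INTENT = 0.4,
                          UNSPEC_UNINTENTIONAL = 0.6, UNSPEC_TRANSPORT = 0.3,
                          UNSPEC_RT = 0.5)
  )
  p <- simulate_panel(cfg)
  res <- redistribute(p$observed, include_level5 = TRUE, rule = same_year_rule)
  expect_lt(max_cell_gap(res$table, p$truth), 1e-9)
})

test_that("conservation ledger accounts for every garbage death", {
  cfg <- sim_config(
    n_countries = 3, years = 2015:2017, total_deaths = 1500,
    sampling = "stochastic", seed = 5,
    garbage_fractions = c(ILL_DEFINED = 0.1, UNSPEC_UNINTENTIONAL = 0.3,
                          UNSPEC_RT = 0.4)
  )
  p <- simulate_panel(cfg)
  res <- redistribute(p$observed, include_level5 = TRUE)
  # all-cause totals per country-year unchanged
  m <- dplyr::inner_join(totals_by_cy(p$observed), totals_by_cy(res$table),
                         by = c("country", "year"))
  expect_lt(max(abs(m$deaths.x - m$deaths.y)), 1e-9)
  # provenance + unallocated == original garbage mass, per category
  garbage_in <- dplyr::summarise(
    dplyr::group_by(
      dplyr::mutate(p$observed, category = icd_classify(cause)),
      category),
    mass = sum(deaths[category != "NONE"]), .groups = "drop")
  ledger <- dplyr::full_join(
    dplyr::summarise(dplyr::group_by(res$provenance, category),
                     placed = sum(added), .groups = "drop"),
    dplyr::summarise(dplyr::group_by(res$unallocated, category),
                     lost = sum(mass), .groups = "drop"),
    by = "category")
  ledger[is.na(ledger)] <- 0
  check <- dplyr::inner_join(
    ledger, garbage_in[garbage_in$category != "NONE", ], by = "category")
  expect_gt(nrow(check), 0)
  expect_lt(max(abs(check$placed + check$lost - check$mass)), 1e-9)
  # table identity: output = specific input + placed mass
  expect_equal(sum(res$table$deaths),
               sum(p$observed$deaths) - sum(ledger$lost), tolerance = 1e-9)
})

test_that("correction never decreases road traffic deaths", {
  cfg <- sim_config(
    n_countries = 5, years = 2015:2017, total_deaths = 3000,
    sampling = "stochastic", seed = 13,
    garbage_fractions = c(ILL_DEFINED = 0.2, UNDETERMINED_INTENT = 0.2,
                          UNSPEC_UNINTENTIONAL = 0.4, UNSPEC_TRANSPORT = 0.3,
                          UNSPEC_RT = 0.3)
  )
  p <- simulate_panel(cfg)
  res <- redistribute(p$observed, include_level5 = TRUE)
  before <- rt_death_series(p$observed)
  after <- rt_death_series(res$table)
  m <- dplyr::inner_join(before, after, by = c("country", "year"))
  expect_true(all(m$deaths.y >= m$deaths.x - 1e-9))
})

test_that("level 5 moves mass only within road traffic", {
  cfg <- sim_config(
    n_countries = 3, years = 2015:2016, total_deaths = 2000,
    garbage_fractions = c(ILL_DEFINED = 0.1, UNSPEC_RT = 0.5)
  )
  p <- simulate_panel(cfg)
  l4 <- redistribute(p$observed, include_level5 = FALSE)
  l5 <- redistribute(p$observed, include_level5 = TRUE)
  # levels 1-4 leave the unspecified-RT rows untouched
  v87 <- l4$table[icd_classify(l4$table$cause) == "UNSPEC_RT", ]
  v87_obs <- p$observed[icd_classify(p$observed$cause) == "UNSPEC_RT", ]
  expect_equal(sum(v87$deaths), sum(v87_obs$deaths), tolerance = 1e-9)
  expect_false(any(icd_classify(l5$table$cause) == "UNSPEC_RT"))
  # overall RT totals agree between the two cascades
  m <- dplyr::inner_join(rt_death_series(l4$table), rt_death_series(l5$table),
                         by = c("country", "year"))
  expect_lt(max(abs(m$deaths.x - m$deaths.y)), 1e-9)
  # level-5 targets are occupants and motorcyclists only
  lvl5 <- res_prov <- l5$provenance[l5$provenance$category == "UNSPEC_RT", ]
  expect_true(all(icd_road_user(unique(lvl5$cause)) %in%
                    c("OCCUPANT", "MOTORCYCLIST")))
})

test_that("empty strata fall back down the pooling ladder", {
  # garbage sits in a (sex, age) stratum with no same-stratum targets;
  # the sexes-pooled fallback places it
  tab <- dplyr::bind_rows(
    mt("R99", 10, sex = "male", age_group = "20-24"),
    mt("I21.9", 30, sex = "female", age_group = "20-24"),
    mt("C34.9", 10, sex = "female", age_group = "20-24")
  )
  res <- redistribute(tab)
  placed <- res$table[res$table$sex == "male", ]
  expect_equal(sum(placed$deaths), 10)
  expect_equal(placed$deaths[placed$cause == "I21.9"], 7.5)
  # no targets anywhere: the mass lands in the unallocated ledger
  lonely <- mt("V87.3", 5)
  expect_warning(res2 <- redistribute(lonely), "unallocated")
  expect_equal(sum(res2$unallocated$mass), 5)
  expect_equal(nrow(res2$table), 0L)
})

test_that("strata mode none uses the country-year cause distribution", {
  tab <- dplyr::bind_rows(
    mt("R99", 10, sex = "male", age_group = "20-24"),
    mt("I21.9", 90, sex = "male", age_group = "20-24"),
    mt("I21.9", 10, sex = "female", age_group = "50-54"),
    mt("C34.9", 90, sex = "female", age_group = "50-54")
  )
  res <- redistribute(tab, strata = "none")
  male <- res$table[res$table$sex == "male", ]
  # weights I21.9 100 / C34.9 90 at the country-year level
  expect_equal(male$deaths[male$cause == "I21.9"], 90 + 10 * 100 / 190)
  expect_equal(male$deaths[male$cause == "C34.9"], 10 * 90 / 190)
})

test_that("tidy and glance expose the ledger", {
  tab <- dplyr::bind_rows(mt("I21.9", 60), mt("C34.9", 40), mt("R99", 10))
  res <- redistribute(tab, rule = same_year_rule)
  td <- generics::tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(sum(td$added), 10)
  gl <- generics::glance(res)
  expect_equal(gl$input_deaths, 110)
  expect_equal(gl$output_deaths, 110)
})
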