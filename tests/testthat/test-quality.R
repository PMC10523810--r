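test_that("availability counts years with any data, absent countries get 0", {
  tab <- dplyr::bind_rows(
    mt("A00", 1, country = "AAA", year = 2015L),
    mt("A00", 1, country = "AAA", year = 2016L),
    mt("A00", 1, country = "AAA", year = 2017L),
    mt("A00", 1, country = "AAA", year = 2018L),
    mt("A00", 1, country = "AAA", year = 2019L),
    mt("A00", 1, country = "AAA", year = 2020L),
    mt("A00", 1, country = "BBB", year = 2016L),
    mt("A00", 1, country = "BBB", year = 2019L),
    mt("A00", 1, country = "CCC", year = 2013L)
  )
  avail <- assess_availability(tab, 2015:2020, countries = c("AAA", "BBB", "CCC", "DDD"))
  expect_equal(avail$years_available[avail$country == "AAA"], 6L)
  expect_equal(avail$years_available[avail$country == "BBB"], 2L)
  expect_equal(avail$years_available[avail$country == "CCC"], 0L)
  expect_equal(avail$years_available[avail$country == "DDD"], 0L)
})

test_that("nonspecific proportions are direct level ratios", {
  # 100 total deaths of which 7 are R99 -> ill-defined 7%
  tab <- dplyr::bind_rows(mt("I21.9", 93), mt("R99", 7))
  q <- nonspecific_proportions(tab)
  expect_equal(q$proportion[q$category == "ILL_DEFINED"], 7.0)
  # 50 road traffic deaths of which 20 are V87.x -> unspecified RT 40%
  tab2 <- dplyr::bind_rows(mt("V43.5", 30), mt("V87.3", 20))
  q2 <- nonspecific_proportions(tab2)
  expect_equal(q2$proportion[q2$category == "UNSPEC_RT"], 40.0)
  # no injury deaths at all -> undetermined intent undefined, never 0
  tab3 <- mt("I21.9", 100)
  q3 <- nonspecific_proportions(tab3)
  expect_true(is.na(q3$proportion[q3$category == "UNDETERMINED_INTENT"]))
  expect_equal(q3$proportion[q3$category == "ILL_DEFINED"], 0)
})

test_that("denominators may include or exclude the level's own garbage", {
  tab <- dplyr::bind_rows(mt("V43.5", 30), mt("V87.3", 20))
  incl <- nonspecific_proportions(tab, include_garbage_in_denominator = TRUE)
  excl <- nonspecific_proportions(tab, include_garbage_in_denominator = FALSE)
  expect_equal(incl$proportion[incl$category == "UNSPEC_RT"], 40)
  expect_equal(excl$proportion[excl$category == "UNSPEC_RT"], 100 * 20 / 30)
})

test_that("proportions are invariant to row order and cell splitting", {
  tab <- dplyr::bind_rows(mt("I21.9", 93), mt("R99", 7))
  split_tab <- dplyr::bind_rows(
    mt("R99", 7),
    mt("I21.9", 50),
    mt("I21.9", 43, age_group = "50-54")
  )
  q1 <- nonspecific_proportions(tab)
  q2 <- nonspecific_proportions(split_tab)
  expect_equal(q1$proportion, q2$proportion)
})

test_that("deterministic injection is recovered by the quality indicator", {
  for (frac in list(c(ILL_DEFINED = 0.1), c(UNDETERMINED_INTENT = 0.25))) {
    cfg <- sim_config(n_countries = 2, years = 2015:2016, total_deaths = 5000,
                      garbage_fractions = frac)
    p <- simulate_panel(cfg)
    q <- nonspecific_proportions(p$observed)
    got <- q$proportion[q$category == names(frac)]
    expect_equal(got, rep(100 * frac[[1]], 4), tolerance = 1e-9)
  }
})

test_that("binning uses upper-inclusive lower bins", {
  expect_equal(as.character(bin_proportions(c(0, 20, 20.5, 40, 60.1, 80, 81, 100))),
               c("P0_20", "P0_20", "P21_40", "P21_40", "P61_80", "P61_80",
                 "P81_100", "P81_100"))
  expect_true(is.na(bin_proportions(NA_real_)))
  expect_error(bin_proportions(101), "outside")
  expect_error(bin_proportions(-2), "outside")
  q <- assess_quality(dplyr::bind_rows(mt("I21.9", 93), mt("R99", 7)))
  expect_equal(as.character(q$bin[q$category == "ILL_DEFINED"]), "P0_20")
})

test_that("garbage mass never exceeds total deaths across categories", {
  cfg <- sim_config(n_countries = 2, years = 2015:2016, total_deaths = 3000,
                    garbage_fractions = c(ILL_DEFINED = 0.3,
                                          UNSPEC_UNINTENTIONAL = 0.5,
                                          UNSPEC_RT = 0.6))
  p <- simulate_panel(cfg)
  q <- nonspecific_proportions(p$observed)
  per_cy <- dplyr::summarise(
    dplyr::group_by(q, country, year),
    garbage = sum(garbage_deaths), .groups = "drop")
  tot <- totals_by_cy(p$observed)
  m <- dplyr::inner_join(per_cy, tot, by = c("country", "year"))
  expect_true(all(m$garbage <= m$deaths + 1e-9))
})

test_that("over-threshold summary averages flagged countries per year", {
  tab <- dplyr::bind_rows(
    mt("I21.9", 70, country = "AAA"), mt("R99", 30, country = "AAA"),
    mt("I21.9", 99, country = "BBB"), mt("R99", 1, country = "BBB"),
    mt("I21.9", 50, country = "AAA", year = 2018L),
    mt("R99", 50, country = "AAA", year = 2018L)
  )
  s <- summarise_over_threshold(assess_quality(tab), threshold = 20)
  # 2017: one country over 20%; 2018: one country over -> mean 1
  expect_equal(
    s$mean_countries_over_threshold[s$category == "ILL_DEFINED"], 1)
})
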