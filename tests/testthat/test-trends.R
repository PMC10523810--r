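test_that("geometric-mean annual change collapses to the endpoint form", {
  expect_equal(geometric_change(c(2015, 2017), c(100, 81))$r, -0.10)
  expect_equal(geometric_change(2015:2020, c(120, 90, 130, 110, 100, 120))$r,
               0)
  expect_equal(geometric_change(2015:2020, rep(7, 6))$r, 0)
  # a series ending at zero deaths: -100% per year
  expect_equal(geometric_change(2015:2020, c(40, 30, 20, 10, 5, 0))$r, -1)
  # intermediate zeros do not poison the endpoint form
  expect_equal(geometric_change(c(2015, 2016, 2017), c(100, 0, 100))$r, 0)
  expect_error(geometric_change(2015, 10), "fewer than two")
  expect_error(geometric_change(c(2015, 2016), c(0, 10)), "first year")
})

test_that("projection chains from the last observed year", {
  tr <- annual_change(tibble::tibble(
    country = "AAA", year = 2015:2018, deaths = c(100, 90, 85, 80)))
  pr <- project_trend(tr)
  r <- tr$r[1]
  expect_equal(pr$deaths_2021, 80 * (1 + r)^3)
  expect_equal(pr$deaths_2030, 80 * (1 + r)^12)
  expect_equal(pr$pct_change_2021_2030, 100 * ((1 + r)^9 - 1))
})

test_that("degenerate trends project to the closed-form limits", {
  # r = -1: everything is zero from the next year on
  tr <- annual_change(tibble::tibble(country = "Z", year = 2015:2020,
                                     deaths = c(40, 30, 20, 10, 5, 0)))
  pr <- project_trend(tr)
  expect_equal(pr$pct_change_2021_2030, -100)
  expect_equal(pr$deaths_2021, 0)
  expect_false(is.na(pr$on_track))
  expect_true(pr$on_track)
  # r = 0: flat forever
  tr0 <- annual_change(tibble::tibble(country = "Z", year = 2015:2020,
                                      deaths = rep(120, 6)))
  pr0 <- project_trend(tr0)
  expect_equal(pr0$pct_change_2021_2030, 0)
  expect_false(pr0$on_track)
  # r = 0.10 compounds to +135.79% over nine years
  pr1 <- project_trend(tibble::tibble(
    country = "Z", r = 0.10, first_year = 2015L, last_year = 2020L,
    n_years_used = 6L, first_deaths = 100, last_deaths = 100 * 1.1^5))
  expect_equal(pr1$pct_change_2021_2030, 135.79, tolerance = 1e-4)
})

test_that("percent change is strictly increasing in r, exponents compose", {
  rs <- seq(-0.99, 0.5, by = 0.01)
  pc <- 100 * ((1 + rs)^9 - 1)
  expect_true(all(diff(pc) > 0))
  # projecting 4 then 5 years equals projecting 9 years at once
  tr <- tibble::tibble(country = "Z", r = -0.07, first_year = 2015L,
                       last_year = 2020L, n_years_used = 6L,
                       first_deaths = 200, last_deaths = 200 * 0.93^5)
  p_2025 <- project_trend(tr, years = c(2021L, 2025L))
  tr2 <- dplyr::mutate(tr, last_year = 2025L,
                       last_deaths = p_2025$deaths_2025)
  p_2030 <- project_trend(tr2, years = c(2026L, 2030L))
  p_direct <- project_trend(tr)
  expect_equal(p_2030$deaths_2030, p_direct$deaths_2030, tolerance = 1e-12)
})

test_that("the on-track boundary sits exactly at a 50% reduction", {
  r_star <- 0.5^(1 / 9) - 1
  tr <- tibble::tibble(country = "Z", r = r_star, first_year = 2015L,
                       last_year = 2020L, n_years_used = 6L,
                       first_deaths = 100, last_deaths = 100)
  pr <- project_trend(tr)
  expect_equal(pr$pct_change_2021_2030, -50)
  expect_true(pr$on_track)
  pr_above <- project_trend(dplyr::mutate(tr, r = r_star + 1e-6))
  expect_false(pr_above$on_track)
})

test_that("trend shifts classify sign flips and >10-point moves", {
  unc <- tibble::tibble(country = c("TUN", "LBN", "NLD", "BMU", "VIR"),
                        r = c(-0.048, 0.545, -0.05, 0, 0))
  cor <- tibble::tibble(country = c("TUN", "LBN", "NLD", "BMU", "VIR"),
                        r = c(0.078, 0.348, -0.05, 0.001, -0.074))
  s <- classify_shift(unc, cor)
  expect_equal(s$shift[s$country == "TUN"], "sign_flip_pos")
  expect_equal(s$shift[s$country == "LBN"], "shift_gt_10pt")
  expect_equal(s$shift[s$country == "NLD"], "minor")
  expect_equal(s$shift[s$country == "BMU"], "sign_flip_pos")
  expect_equal(s$shift[s$country == "VIR"], "sign_flip_neg")
})

test_that("countries without a defined trend are flagged, not dropped silently", {
  series <- tibble::tibble(
    country = c("AAA", "AAA", "BBB", "CCC", "CCC"),
    year = c(2015L, 2016L, 2015L, 2015L, 2016L),
    deaths = c(10, 12, 5, 0, 4))
  expect_warning(tr <- annual_change(series), "BBB")
  expect_true(is.na(tr$r[tr$country == "BBB"]))
  expect_true(is.na(tr$r[tr$country == "CCC"]))
  expect_equal(tr$r[tr$country == "AAA"], 0.2)
  pr <- project_trend(tr)
  expect_equal(pr$country, "AAA")
})
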