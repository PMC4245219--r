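test_that("break-up month is the first month below the 50% threshold", {
  expect_equal(breakup_month(c(100, 100, 95, 80, 45, 20, 5, 5, 20, 60, 90, 100)), 5L)
  expect_true(is.na(breakup_month(rep(95, 12))))
  expect_equal(breakup_month(rep(5, 12)), 1L)
  expect_equal(breakup_month(rep(50, 12)), NA_integer_)  # strict <
  expect_equal(breakup_month(rep(49.999, 12)), 1L)
  expect_error(breakup_month(rep(5, 10)), "12 months")
})

test_that("printed edge cases: all-below-10 gives twelve months, never-below-10 gives zero", {
  all_low <- ice_free_season(rep(5, 12), rep(5, 12))
  expect_equal(all_low$length_months, 12L)
  all_high <- ice_free_season(rep(30, 12), rep(30, 12))
  expect_equal(all_high$length_months, 0L)
  expect_equal(all_high$length_days, 0)
  # the same holds without a following year (last year of record)
  expect_equal(ice_free_season(rep(5, 12))$length_months, 12L)
  expect_equal(ice_free_season(rep(95, 12))$length_months, 0L)
})

test_that("hand-traced season: May break-up, September freeze-up, 123 days", {
  s <- c(100, 100, 90, 70, 40, 8, 5, 6, 15, 70, 95, 100)
  ps <- ice_free_season(s, year = 2001, calendar = "standard")
  expect_equal(ps$breakup_month, 5L)
  expect_equal(ps$freezeup_month, 9L)
  expect_equal(ps$length_months, 4L)
  expect_equal(ps$length_days, 123)  # May+Jun+Jul+Aug
  # a noleap calendar gives the same sum for these months
  expect_equal(ice_free_season(s, calendar = "noleap")$length_days, 123)
  # leap February inside the season is counted
  w <- c(5, 5, 5, 5, 5, 5, 5, 5, 5, 5, 5, 5)
  expect_equal(ice_free_season(w, year = 2004, calendar = "standard")$length_days, 366)
  expect_equal(ice_free_season(w, year = 2004, calendar = "noleap")$length_days, 365)
})

test_that("seasons wrap into the following year and cap at twelve months", {
  # break-up in November; ice returns the following March
  cur <- c(rep(100, 10), 40, 5)
  nxt <- c(5, 5, 15, 60, 90, 100, 100, 100, 100, 100, 100, 100)
  ps <- ice_free_season(cur, nxt)
  expect_equal(ps$breakup_month, 11L)
  expect_equal(ps$freezeup_month, 15L)  # March of the following year
  expect_equal(ps$length_months, 4L)
  # ice never returns within 12 months: capped
  ps2 <- ice_free_season(cur, rep(5, 12))
  expect_equal(ps2$length_months, 12L)
  # a missing month inside the search window flags the season missing
  cur_na <- cur; cur_na[12] <- NA
  expect_true(is.na(ice_free_season(cur_na, nxt)$length_months))
})

test_that("season lengths match a brute-force month scan on random series", {
  set.seed(403)
  for (rep in 1:10000) {
    series <- c(random_sic_year(), random_sic_year())
    got <- ice_free_season(series[1:12], series[13:24])
    want <- oracle_season_months(series)
    expect_identical(got$length_months, want$length)
    expect_identical(got$breakup_month, want$breakup)
  }
  # last-year truncation path
  for (rep in 1:2000) {
    series <- random_sic_year()
    got <- ice_free_season(series)
    want <- oracle_season_months(series)
    expect_identical(got$length_months, want$length)
  }
})

test_that("uniformly lowering a seasonal cycle never shortens the season", {
  # the guarantee applies to winter-saturated single-dip cycles (monotone
  # from January down to the summer minimum); shapes whose January flank
  # can fall below 10% while a later winter month stays above it may
  # legitimately shorten, because only the first ice-free period is scored
  set.seed(404)
  for (rep in 1:500) {
    wm <- runif(1, 40, 100)
    sm <- runif(1, 0, wm)
    yr <- pmin(pmax(seasonal_template_for_tests(wm, sm) +
                      runif(1, -5, 5), 0), 100)
    series <- rep(yr, 2)
    lowered <- pmax(series - runif(1, 0, 60), 0)
    l0 <- ice_free_season(series[1:12], series[13:24])$length_months
    l1 <- ice_free_season(lowered[1:12], lowered[13:24])$length_months
    expect_gte(l1, l0)
  }
})

test_that("fieldset phenology handles uniform fields and stays in bounds", {
  per <- uniform_fieldset(seasonal_template_for_tests(100, 60), years = 2)
  phen <- phenology_fieldset(per)
  expect_true(all(phen$length_months == 0))

  low <- uniform_fieldset(rep(5, 12), years = 2)
  phen_low <- phenology_fieldset(low)
  expect_true(all(phen_low$length_months == 12))
  expect_true(all(phen_low$length_days >= 365))

  sc <- generate_scenario(scenario_config(ny = 6, nx = 6, start_year = 2030,
                                          end_year = 2036, seed = 31))
  phen_sc <- phenology_fieldset(sc$fields)
  nyr <- length(phen_sc$years)
  lm <- matrix(phen_sc$length_months, nrow = nyr)[, !as.vector(sc$fields$land_mask)]
  expect_true(all(lm >= 0 & lm <= 12, na.rm = TRUE))
  expect_true(all(phen_sc$length_days <= 366, na.rm = TRUE))
})

test_that("noise-free scenarios give nondecreasing regional season lengths", {
  cfg <- scenario_config(ny = 6, nx = 6, start_year = 2000, end_year = 2060,
                         seed = 1, noise_sd = 0,
                         regions = data.frame(name = "r1", winter_max_sic = 100,
                                              summer_min_sic_start = 60,
                                              melt_out_year = 2020))
  sc <- generate_scenario(cfg)
  phen <- phenology_fieldset(sc$fields)
  i <- 3; j <- 3
  lens <- phen$length_months[, i, j]
  expect_true(all(diff(lens) >= 0))
})
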