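test_that("critical categories follow the day and break-up-month thresholds", {
  none <- classify_critical(list(length_days = 0, breakup_month = NA))
  expect_false(any(none))
  c_only <- classify_critical(list(length_days = 100, breakup_month = 7))
  expect_equal(unname(c_only), c(FALSE, FALSE, TRUE, FALSE))
  all4 <- classify_critical(list(length_days = 185, breakup_month = 5))
  expect_true(all(all4))
  # >= at the exact day boundaries, <= at the month boundaries
  expect_true(classify_critical(list(length_days = 120, breakup_month = 9))[["A"]])
  expect_false(classify_critical(list(length_days = 119, breakup_month = 9))[["A"]])
  expect_true(classify_critical(list(length_days = 180, breakup_month = 9))[["B"]])
  expect_false(classify_critical(list(length_days = 179, breakup_month = 9))[["B"]])
  expect_true(classify_critical(list(length_days = 0, breakup_month = 6))[["D"]])
  expect_false(classify_critical(list(length_days = 0, breakup_month = 8))[["C"]])
  expect_true(all(is.na(classify_critical(list(length_days = NA,
                                               breakup_month = NA)))))
})

test_that("severity nesting holds for every season: B implies A, D implies C", {
  set.seed(405)
  for (rep in 1:1000) {
    season <- list(length_days = runif(1, 0, 366),
                   breakup_month = sample(c(NA, 1:12), 1))
    fl <- classify_critical(season)
    if (isTRUE(fl[["B"]])) expect_true(fl[["A"]])
    if (isTRUE(fl[["D"]])) expect_true(fl[["C"]])
  }
})

test_that("raising the day threshold can never add events", {
  set.seed(406)
  lax <- threshold_config(critical_a_days = 100)
  strict <- threshold_config(critical_a_days = 150)
  for (rep in 1:300) {
    season <- list(length_days = runif(1, 0, 366), breakup_month = 7)
    if (classify_critical(season, strict)[["A"]]) {
      expect_true(classify_critical(season, lax)[["A"]])
    }
  }
})

test_that("point of no return matches the exhaustive suffix scan", {
  expect_equal(point_of_no_return(c(F, F, T, T, T), 2006:2010), 2008L)
  expect_equal(point_of_no_return(c(F, T, F, T, T), 2006:2010), 2009L)
  expect_true(is.na(point_of_no_return(c(T, F, F, F, F), 2006:2010)))
  expect_error(point_of_no_return(logical(0), integer(0)), "empty")
  # every boolean sequence of length 10
  years <- 2001:2010
  for (code in 0:1023) {
    flags <- as.logical(bitwAnd(bitwShiftR(code, 0:9), 1L))
    expect_identical(point_of_no_return(flags, years),
                     oracle_ponr(flags, years))
  }
})

test_that("point of no return satisfies its defining postcondition", {
  set.seed(407)
  years <- 2006:2100
  for (rep in 1:200) {
    flags <- runif(length(years)) < 0.4
    y <- point_of_no_return(flags, years)
    if (!is.na(y)) {
      expect_true(all(flags[years >= y]))
      if (y > years[1]) expect_false(flags[which(years == y) - 1L])
    } else {
      expect_false(flags[length(flags)])
    }
  }
})

test_that("cumulative counts match a brute-force double loop and add up", {
  single <- cumulative_events(matrix(c(TRUE, FALSE, TRUE), ncol = 1), 1:3)
  expect_equal(single$cumulative[single$region != "total"], c(1, 1, 2))
  two <- cumulative_events(cbind(c(TRUE, FALSE), c(FALSE, FALSE)), 1:2)
  expect_equal(two$cumulative[two$region == "total"], c(1, 1))

  set.seed(408)
  years <- 2006:2100
  flags <- array(runif(length(years) * 7 * 4) < 0.3,
                 c(length(years), 7, 4),
                 dimnames = list(NULL, NULL, c("A", "B", "C", "D")))
  got <- cumulative_events(flags, years, region_names = paste0("r", 1:7))
  for (cat in c("A", "B", "C", "D")) {
    want <- oracle_cumulative(flags[, , cat])
    for (r in 1:7) {
      sub <- got[got$category == cat & got$region == paste0("r", r), ]
      expect_equal(sub$cumulative, want[, r])
    }
    tot <- got[got$category == cat & got$region == "total", ]
    expect_equal(tot$cumulative, rowSums(want))
    expect_true(all(diff(tot$cumulative) >= 0))
  }
  expect_error(cumulative_events(flags, 1:3), "misaligned")
})

test_that("homogeneous regions trigger identically in both event modes", {
  # every marine pixel melts out below 10% June-August, back above in Sept
  yr <- c(100, 100, 90, 60, 30, 8, 4, 6, 20, 70, 95, 100)
  fs <- uniform_fieldset(yr, years = 3)
  mask <- single_region_mask()
  mean_mode <- region_year_critical(fs, mask, 1, threshold_config())
  frac_mode <- region_year_critical(
    fs, mask, 1, threshold_config(region_event_mode = "pixel_fraction"))
  expect_identical(mean_mode, frac_mode)
  expect_true(mean_mode[1, "A"])   # May-Aug season: 123 days >= 120
  expect_false(mean_mode[1, "B"])
  expect_true(mean_mode[1, "C"])   # break-up in May
  expect_true(mean_mode[1, "D"])
})

test_that("split regions separate the two region-event modes", {
  # half the area ice-free all year, half perennial at 100%
  nt <- 36L
  sic <- array(NA_real_, c(nt, 2, 2))
  sic[, 1, ] <- 5
  sic[, 2, ] <- 100
  fs <- ice_fieldset(sic, start_year = 2000)
  mask <- single_region_mask(ny = 2, nx = 2)
  frac <- region_year_critical(
    fs, mask, 1,
    threshold_config(region_event_mode = "pixel_fraction",
                     pixel_fraction_cutoff = 0.5))
  expect_true(all(frac[, "B"]))    # half the area is critical: 0.5 >= cutoff
  # the regional mean SIC is 52.5 year-round, never below 10: no season
  mean_mode <- region_year_critical(fs, mask, 1, threshold_config())
  expect_false(any(mean_mode))
})
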