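test_that("period climatology of a constant field is the field", {
  fs <- uniform_fieldset(rep(80, 12), years = 6, start_year = 2000)
  mask <- single_region_mask()
  clim <- period_climatology(fs, mask, periods = list(c(2000, 2005)))
  expect_true(all(clim$value[clim$variable == "sic"] == 80))
  expect_equal(nrow(clim), 12L)
  expect_error(period_climatology(fs, mask, periods = list(c(1990, 1995))),
               "outside record")
})

test_that("climatology averages across period years and weights by area", {
  # two years whose Januaries differ: 90 then 70
  s <- array(80, c(24, 1, 2))
  s[1, , ] <- 90; s[13, , ] <- 70
  fs <- ice_fieldset(s, start_year = 2000)
  clim <- period_climatology(fs, single_region_mask(ny = 1, nx = 2),
                             periods = list(c(2000, 2001)))
  expect_equal(clim$value[clim$month == 1], 80)

  # cell areas 1 and 3 with values 0 and 100: weighted mean 75
  s2 <- array(rep(c(0, 100), each = 12), c(12, 1, 2))
  fs2 <- ice_fieldset(s2, start_year = 2000)
  mask2 <- region_mask(matrix(1L, 1, 2), names = "only",
                       cell_area = matrix(c(1, 3), 1, 2))
  clim2 <- period_climatology(fs2, mask2, periods = list(c(2000, 2000)))
  expect_true(all(clim2$value == 75))
})

test_that("ice-type proportions count area and sum to one", {
  cls <- array(0L, c(1, 2, 2))
  cls[1, , ] <- c(1L, 1L, 2L, 3L)  # 2 multiyear, 1 annual, 1 ice_free
  cm <- structure(list(class = cls, years = 2000L), class = "ice_class_map")
  pr <- ice_type_proportions(cm, single_region_mask(ny = 2, nx = 2))
  one <- pr[pr$region == "only", ]
  expect_equal(c(one$multiyear, one$annual, one$ice_free),
               c(0.50, 0.25, 0.25))

  cls[1, , ] <- 1L
  cm$class <- cls
  pr_all <- ice_type_proportions(cm, single_region_mask(ny = 2, nx = 2))
  expect_equal(pr_all$multiyear[1], 1)

  # unequal areas (1, 1, 2) for (multiyear, annual, ice_free)
  cls3 <- array(c(1L, 2L, 3L), c(1, 1, 3))
  cm3 <- structure(list(class = cls3, years = 2000L),
                   class = "ice_class_map")
  mask3 <- region_mask(matrix(1L, 1, 3), names = "only",
                       cell_area = matrix(c(1, 1, 2), 1, 3))
  pr3 <- ice_type_proportions(cm3, mask3)
  expect_equal(c(pr3$multiyear[1], pr3$annual[1], pr3$ice_free[1]),
               c(0.25, 0.25, 0.50))

  # proportions sum to 1 over classified area on a full scenario
  sc <- generate_scenario(scenario_config(ny = 8, nx = 8, start_year = 2030,
                                          end_year = 2040, seed = 13))
  pr_sc <- ice_type_proportions(classify_fieldset(sc$fields), sc$mask)
  sums <- pr_sc$multiyear + pr_sc$annual + pr_sc$ice_free
  expect_true(all(abs(sums - 1) < 1e-9, na.rm = TRUE))
  # all-missing pixels flag undefined
  cls0 <- array(0L, c(1, 2, 2))
  cm0 <- structure(list(class = cls0, years = 2000L),
                   class = "ice_class_map")
  pr0 <- ice_type_proportions(cm0, single_region_mask(ny = 2, nx = 2))
  expect_true(all(is.na(pr0$multiyear)))
})

test_that("seal-habitat flag uses >= 20 cm mean April snow over ice", {
  base <- rep(80, 12)
  deep <- uniform_fieldset(base, years = 1,
                           snow = array(0.25, c(12, 4, 4)))
  shallow <- uniform_fieldset(base, years = 1,
                              snow = array(0.10, c(12, 4, 4)))
  exact <- uniform_fieldset(base, years = 1,
                            snow = array(0.20, c(12, 4, 4)))
  mask <- single_region_mask()
  expect_true(seal_habitat_flag(deep, mask)$seal_habitat)
  expect_false(seal_habitat_flag(shallow, mask)$seal_habitat)
  expect_true(seal_habitat_flag(exact, mask)$seal_habitat)  # minimum 20 cm
  # no ice-covered pixels in April: false, with a warning
  open <- uniform_fieldset(rep(5, 12), years = 1,
                           snow = array(0.5, c(12, 4, 4)))
  expect_warning(flag <- seal_habitat_flag(open, mask), "no ice-covered")
  expect_false(flag$seal_habitat)
})

test_that("break-up area fraction is weighted and monotone in month", {
  # half the area (by weight) breaks up in May, the rest never
  nt <- 12L
  sic <- array(100, c(nt, 1, 2))
  sic[5:9, , 1] <- 5
  fs <- ice_fieldset(sic, start_year = 2000)
  mask <- region_mask(matrix(1L, 1, 2), names = "only",
                      cell_area = matrix(c(2, 2), 1, 2))
  phen <- phenology_fieldset(fs)
  expect_equal(breakup_area_fraction(phen, mask, month = 7)$fraction, 0.5)
  expect_equal(breakup_area_fraction(phen, mask, month = 4)$fraction, 0.0)

  all_june <- uniform_fieldset(c(rep(100, 5), rep(5, 4), rep(100, 3)),
                               years = 1)
  phen_june <- phenology_fieldset(all_june)
  m4 <- single_region_mask()
  expect_equal(breakup_area_fraction(phen_june, m4, month = 7)$fraction, 1.0)
  none <- uniform_fieldset(rep(95, 12), years = 1)
  expect_equal(breakup_area_fraction(phenology_fieldset(none), m4,
                                     month = 7)$fraction, 0.0)

  sc <- generate_scenario(scenario_config(ny = 8, nx = 8, start_year = 2030,
                                          end_year = 2035, seed = 17))
  phen_sc <- phenology_fieldset(sc$fields)
  fr <- sapply(1:12, function(m) {
    breakup_area_fraction(phen_sc, sc$mask, month = m)$fraction[1]
  })
  expect_true(all(diff(fr) >= 0))
})
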