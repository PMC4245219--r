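# Brute-force reference implementations: literal month-by-month scans of
# the published rules, kept independent of the package's vectorized /
# short-circuited code paths.

oracle_classify <- function(cur, prior = NULL, presence = 15) {
  if (any(is.na(cur))) return("missing")
  n_at_or_above <- 0L
  for (m in 1:12) if (cur[m] >= presence) n_at_or_above <- n_at_or_above + 1L
  if (n_at_or_above == 12L) return("multiyear")
  prior_ice <- FALSE
  if (!is.null(prior)) {
    for (m in 1:12) {
      if (!is.na(prior[m]) && prior[m] >= presence) prior_ice <- TRUE
    }
  }
  if (n_at_or_above == 0L && !prior_ice) return("ice_free")
  "annual"
}

# scans the concatenated 24-month (or 12-month) series explicitly
oracle_season_months <- function(series, breakup = 50, freezeup = 10) {
  b <- NA_integer_
  for (m in 1:12) {
    if (series[m] < breakup) { b <- m; break }
  }
  if (is.na(b)) return(list(breakup = NA_integer_, length = 0L))
  horizon <- min(b + 12L, length(series))
  dropped <- FALSE
  f <- NA_integer_
  for (m in b:horizon) {
    if (series[m] < freezeup) dropped <- TRUE
    if (m > 1 && series[m] >= freezeup && series[m - 1] < freezeup) {
      f <- m; break
    }
  }
  if (!dropped && is.na(f)) return(list(breakup = b, length = 0L))
  if (is.na(f)) f <- horizon + 1L
  list(breakup = b, length = min(f - b, 12L))
}

oracle_ponr <- function(flags, years) {
  n <- length(flags)
  for (y in seq_len(n)) {
    if (all(flags[y:n])) return(as.integer(years[y]))
  }
  NA_integer_
}

oracle_cumulative <- function(flag_matrix) {
  out <- matrix(0, nrow(flag_matrix), ncol(flag_matrix))
  for (r in seq_len(ncol(flag_matrix))) {
    tot <- 0L
    for (y in seq_len(nrow(flag_matrix))) {
      if (isTRUE(flag_matrix[y, r])) tot <- tot + 1L
      out[y, r] <- tot
    }
  }
  out
}

# random 12-month SIC series with mass around the decision thresholds
random_sic_year <- function() {
  v <- runif(12, 0, 100)
  snap <- runif(12) < 0.3
  v[snap] <- sample(c(5, 9, 10, 11, 14, 15, 16, 49, 50, 51),
                    sum(snap), replace = TRUE)
  v
}

# tiny uniform fieldset: every marine pixel carries the same monthly series
uniform_fieldset <- function(series_year, years = 1, ny = 4, nx = 4,
                             start_year = 2000, calendar = "standard",
                             snow = NULL, thickness = NULL) {
  nt <- 12L * years
  s <- rep_len(series_year, nt)
  sic <- array(rep(s, ny * nx), c(nt, ny, nx))
  ice_fieldset(sic, start_year = start_year, calendar = calendar,
               snow = snow, thickness = thickness)
}

single_region_mask <- function(ny = 4, nx = 4, cell_area = NULL) {
  region_mask(matrix(1L, ny, nx), names = "only", cell_area = cell_area)
}

# winter-saturated seasonal cycle (flat plateau at the maximum), the shape
# family the generator emulates
seasonal_template_for_tests <- function(winter_max, summer_min, phase = 9) {
  m <- 1:12
  raw <- summer_min + 1.4 * (winter_max - summer_min) *
    (1 - cos(2 * pi * (m - phase) / 12)) / 2
  pmin(raw, winter_max)
}
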