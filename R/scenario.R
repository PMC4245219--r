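#' Synthetic scenario configuration
#'
#' Describes a seeded statistical emulation of a downscaled high-emissions
#' sea-ice projection: a clipped-sinusoid seasonal SIC cycle per region
#' (winter maximum, summer minimum, minimum month), a secular decline
#' applied as a uniform shift of the whole cycle, spatially correlated
#' interannual noise, and ice thickness and snow depth tied to the
#' noise-free SIC through monotone link functions. The default is a
#' 20 x 20 grid with a one-pixel land frame, seven latitudinal population
#' bands over 1992-2100, and region melt-out years ordered south before
#' north, mirroring the archipelago's north-south ice-persistence
#' gradient.
#'
#' Per region, the decline rate (%/decade) may be given directly or
#' derived from `melt_out_year`, the year the summer minimum first reaches
#' zero: `rate = 10 * summer_min_sic_start / (melt_out_year - start_year)`.
#'
#' @param ny,nx grid shape.
#' @param start_year,end_year simulated calendar years (inclusive).
#' @param seed integer; fixes all randomness.
#' @param regions `data.frame` with one row per region: `name`,
#'   `winter_max_sic`, `summer_min_sic_start` (%), `melt_out_year` (or
#'   `decline_rate` in %/decade), `seasonal_phase` (month of the SIC
#'   minimum, default September). `NULL` selects the seven-region default.
#' @param noise_sd interannual noise standard deviation (% SIC).
#' @param noise_corr_length spatial correlation length of the noise, in
#'   pixels (box-kernel half-width).
#' @param thickness_scale,snow_scale link scales (m): thickness =
#'   `thickness_scale * (annual-mean noise-free SIC / 100)^2`, snow
#'   analogous.
#' @param cell_area_km2 nominal grid-cell area (km^2; an 18 km grid).
#' @param calendar `"noleap"` (typical of climate-model output) or
#'   `"standard"`.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(ny = 20, nx = 20, start_year = 1992,
                            end_year = 2100, seed = 1, regions = NULL,
                            noise_sd = 2, noise_corr_length = 2,
                            thickness_scale = 3, snow_scale = 0.45,
                            cell_area_km2 = 324,
                            calendar = c("noleap", "standard")) {
  calendar <- match.arg(calendar)
  if (ny < 3 || nx < 3) stop("degenerate grid", call. = FALSE)
  if (end_year - start_year + 1 < 2) stop("years span < 2", call. = FALSE)
  if (is.null(regions)) {
    regions <- data.frame(
      # south to north; southern regions melt out first
      name = c("Gulf of Boothia", "M'Clintock Channel", "Lancaster Sound",
               "Viscount Melville", "Kane Basin", "Norwegian Bay",
               "Queen Elizabeth"),
      winter_max_sic = 100,
      summer_min_sic_start = 60,
      melt_out_year = c(2025, 2031, 2037, 2043, 2049, 2055, 2060),
      seasonal_phase = 9
    )
  }
  if (!"decline_rate" %in% names(regions)) {
    regions$decline_rate <- 10 * regions$summer_min_sic_start /
      (regions$melt_out_year - start_year)
  }
  if (!"seasonal_phase" %in% names(regions)) regions$seasonal_phase <- 9
  stopifnot(all(regions$summer_min_sic_start >= 0),
            all(regions$summer_min_sic_start <= regions$winter_max_sic),
            all(regions$winter_max_sic <= 100))
  cfg <- list(ny = ny, nx = nx, start_year = start_year, end_year = end_year,
              seed = seed, regions = regions, noise_sd = noise_sd,
              noise_corr_length = noise_corr_length,
              thickness_scale = thickness_scale, snow_scale = snow_scale,
              cell_area_km2 = cell_area_km2, calendar = calendar)
  class(cfg) <- "scenario_config"
  cfg
}

# Clipped sinusoid with its minimum at month `phase`: the raw cycle
# overshoots the winter maximum by 40% of the range and is clipped there,
# producing a flat winter plateau (roughly January-May for a September
# minimum). Winter Arctic SIC saturates near its maximum for months at a
# time, and the plateau also keeps each year's series monotone from
# January down to the summer minimum, so the first upward 10% crossing —
# freeze-up — can only happen on the autumn flank.
seasonal_template <- function(winter_max, summer_min, phase = 9) {
  m <- 1:12
  raw <- summer_min + 1.4 * (winter_max - summer_min) *
    (1 - cos(2 * pi * (m - phase) / 12)) / 2
  pmin(raw, winter_max)
}

# spatially correlated unit-variance field: box-smoothed white noise,
# rescaled to the requested sd (empirical, so the sd is exact per field)
correlated_noise <- function(ny, nx, corr_length, sd_target) {
  z <- matrix(stats::rnorm(ny * nx), ny, nx)
  if (corr_length > 0) {
    k <- as.integer(corr_length)
    sm <- matrix(0, ny, nx)
    cnt <- matrix(0, ny, nx)
    for (di in -k:k) {
      for (dj in -k:k) {
        si <- max(1, 1 + di):min(ny, ny + di)
        ti <- si - di
        sj <- max(1, 1 + dj):min(nx, nx + dj)
        tj <- sj - dj
        sm[ti, tj] <- sm[ti, tj] + z[si, sj]
        cnt[ti, tj] <- cnt[ti, tj] + 1
      }
    }
    z <- sm / cnt
  }
  s <- stats::sd(as.numeric(z))
  if (s == 0) return(z * 0)
  z / s * sd_target
}

#' Generate a synthetic gridded scenario
#'
#' Builds an [ice_fieldset] (SIC, thickness, snow) and matching
#' [region_mask] from a [scenario_config()]. Monthly SIC is the region's
#' seasonal template, shifted down by the accumulated decline and
#' perturbed by a per-year spatially correlated anomaly shared by the
#' year's twelve months, then clipped to `[0, 100]`. Thickness and snow
#' are quadratic functions of the clipped noise-free annual-mean SIC plus
#' their own noise, clipped at zero. Identical configurations and seeds
#' give bit-identical output.
#'
#' @param config a [scenario_config()].
#' @return list with elements `fields` ([ice_fieldset]) and `mask`
#'   ([region_mask]).
#' @export
generate_scenario <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  ny <- config$ny; nx <- config$nx
  years <- config$start_year:config$end_year
  nyr <- length(years)
  nreg <- nrow(config$regions)

  # one-pixel land frame; interior rows split into latitudinal bands,
  # region 1 (south) at y = 2, region nreg (north) at y = ny - 1
  land <- matrix(FALSE, ny, nx)
  land[c(1, ny), ] <- TRUE
  land[, c(1, nx)] <- TRUE
  labels <- matrix(0L, ny, nx)
  interior <- 2:(ny - 1)
  band <- ceiling(seq_along(interior) * nreg / length(interior))
  for (r in seq_along(interior)) labels[interior[r], 2:(nx - 1)] <- band[r]
  # mild poleward area taper so weighting is exercised
  area_row <- config$cell_area_km2 * (1 - 0.15 * (seq_len(ny) - 1) / (ny - 1))
  cell_area <- matrix(rep(area_row, nx), ny, nx)
  mask <- region_mask(labels, names = config$regions$name,
                      cell_area = cell_area)

  templ <- sapply(seq_len(nreg), function(r) {
    seasonal_template(config$regions$winter_max_sic[r],
                      config$regions$summer_min_sic_start[r],
                      config$regions$seasonal_phase[r])
  })  # 12 x nreg
  delta <- outer(years - config$start_year,
                 config$regions$decline_rate / 10)  # nyr x nreg

  sic <- array(NA_real_, c(12 * nyr, ny, nx))
  thickness <- array(NA_real_, c(12 * nyr, ny, nx))
  snow <- array(NA_real_, c(12 * nyr, ny, nx))
  reg_of_pixel <- labels
  for (k in seq_len(nyr)) {
    anom <- correlated_noise(ny, nx, config$noise_corr_length,
                             config$noise_sd)
    th_noise <- matrix(stats::rnorm(ny * nx, sd = 0.05 * config$thickness_scale),
                       ny, nx)
    sn_noise <- matrix(stats::rnorm(ny * nx, sd = 0.05 * config$snow_scale),
                       ny, nx)
    tt <- (k - 1L) * 12L + 1:12
    for (r in seq_len(nreg)) {
      sel <- reg_of_pixel == r
      if (!any(sel)) next
      clean <- pmin(pmax(templ[, r] - delta[k, r], 0), 100)  # 12 months
      am <- mean(clean)  # noise-free annual mean after clipping
      th <- config$thickness_scale * (am / 100)^2
      sn <- config$snow_scale * (am / 100)^2
      idx <- which(sel)
      for (p in idx) {
        i <- (p - 1L) %% ny + 1L; j <- (p - 1L) %/% ny + 1L
        sic[tt, i, j] <- pmin(pmax(clean + anom[i, j], 0), 100)
        thickness[tt, i, j] <- max(th + th_noise[i, j], 0)
        snow[tt, i, j] <- max(sn + sn_noise[i, j], 0)
      }
    }
  }
  fields <- ice_fieldset(sic, start_year = config$start_year,
                         thickness = thickness, snow = snow,
                         land_mask = land, calendar = config$calendar)
  list(fields = fields, mask = mask)
}

#' Generate a single-pixel archetype SIC series
#'
#' Monthly SIC series for unit-test fixtures: `"perennial"` keeps SIC at
#' or above 15% in every month; `"seasonal"` melts out below 15% each
#' summer with winter recovery; `"ice_free"` stays below 15% year-round;
#' `"transitional"` is perennial until `melt_out_year`, seasonal from then
#' on, and fully ice-free from `icefree_year` when given. Noise is
#' bounded (uniform on +/-3%) so every archetype contract holds for every
#' seed.
#'
#' @param archetype one of `"perennial"`, `"seasonal"`, `"ice_free"`,
#'   `"transitional"`.
#' @param years number of years.
#' @param seed integer seed.
#' @param melt_out_year transitional only: first seasonal year (index,
#'   1-based).
#' @param icefree_year transitional only: first fully ice-free year, or
#'   `NULL`.
#' @return numeric vector of `12 * years` monthly SIC values (%).
#' @export
generate_pixel_series <- function(archetype = c("perennial", "seasonal",
                                                "ice_free", "transitional"),
                                  years, seed = 1,
                                  melt_out_year = NULL, icefree_year = NULL) {
  archetype <- match.arg(archetype)
  set.seed(seed)
  perennial <- seasonal_template(100, 60)
  seasonal <- seasonal_template(90, 2)
  icefree <- rep(6, 12)
  base <- switch(archetype,
    perennial = rep(perennial, years),
    seasonal = rep(seasonal, years),
    ice_free = rep(icefree, years),
    transitional = {
      if (is.null(melt_out_year)) {
        stop("transitional archetype needs melt_out_year", call. = FALSE)
      }
      unlist(lapply(seq_len(years), function(y) {
        if (!is.null(icefree_year) && y >= icefree_year) return(icefree)
        if (y >= melt_out_year) seasonal else perennial
      }))
    })
  pmin(pmax(base + stats::runif(length(base), -3, 3), 0), 100)
}
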