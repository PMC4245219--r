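#' Critical ice-free categories of one season
#'
#' Four critical categories tie the ice-free season to polar bear
#' energetics: starvation risk in adult males when the season reaches 120
#' (A) or 180 (B) days, and reproductive-failure risk in females when
#' break-up comes by July (C) or by June (D). Day thresholds compare with
#' `>=`; break-up months with `<=`, so an earlier break-up — strictly worse
#' for bears — always remains critical and severities nest (B implies A,
#' D implies C). A year with no break-up triggers neither C nor D.
#'
#' @param season a season record from [ice_free_season()] (needs
#'   `length_days` and `breakup_month`).
#' @param thresholds a [threshold_config()].
#' @return named logical vector `c(A=, B=, C=, D=)`; all `NA` for a missing
#'   season.
#' @export
#' @examples
#' classify_critical(list(length_days = 185, breakup_month = 5))
classify_critical <- function(season, thresholds = threshold_config()) {
  d <- season$length_days
  b <- season$breakup_month
  if (is.null(d) || is.na(d)) {
    return(c(A = NA, B = NA, C = NA, D = NA))
  }
  c(A = d >= thresholds$critical_a_days,
    B = d >= thresholds$critical_b_days,
    C = !is.na(b) && b <= thresholds$critical_c_month,
    D = !is.na(b) && b <= thresholds$critical_d_month)
}

#' Point of no return of a yearly flag series
#'
#' The first year from which a critical condition holds in every
#' subsequent year of the record: the smallest year `y` with the flag true
#' for all years at or after `y`. If the final year is not critical there
#' is no point of no return. Missing flags count as not critical.
#'
#' @param flags logical vector of yearly critical flags, in year order.
#' @param years matching integer years.
#' @return a year, or `NA_integer_` if none.
#' @export
#' @examples
#' point_of_no_return(c(FALSE, FALSE, TRUE, TRUE, TRUE), 2006:2010)  # 2008
point_of_no_return <- function(flags, years) {
  if (length(flags) == 0) stop("empty flag series", call. = FALSE)
  stopifnot(length(flags) == length(years))
  flags <- !is.na(flags) & flags
  if (!flags[length(flags)]) return(NA_integer_)
  # walk back through the trailing run of TRUE
  y <- length(flags)
  while (y > 1 && flags[y - 1]) y <- y - 1
  as.integer(years[y])
}

#' Cumulative critical-event counts by region and category
#'
#' Running per-region sums of yearly critical flags, plus an all-region
#' total, mirroring stacked cumulative-event curves by population.
#'
#' @param flags_by_region logical array `(year, region, category)` or a
#'   `(year, region)` matrix for a single category.
#' @param years integer years matching the first dimension.
#' @param region_names optional region names.
#' @return `data.frame` with columns `year`, `region`, `category`,
#'   `cumulative`; region `"total"` carries the across-region sum.
#' @export
cumulative_events <- function(flags_by_region, years, region_names = NULL) {
  if (is.matrix(flags_by_region)) {
    dim(flags_by_region) <- c(dim(flags_by_region), 1L)
    dimnames(flags_by_region) <- list(NULL, NULL, "A")
  }
  d <- dim(flags_by_region)
  if (d[1] != length(years)) stop("misaligned years", call. = FALSE)
  cats <- dimnames(flags_by_region)[[3]]
  if (is.null(cats)) cats <- LETTERS[seq_len(d[3])]
  if (is.null(region_names)) region_names <- paste0("region_", seq_len(d[2]))
  out <- list()
  for (k in seq_len(d[3])) {
    fl <- flags_by_region[, , k, drop = FALSE]
    dim(fl) <- d[1:2]
    fl[is.na(fl)] <- FALSE
    cum <- apply(fl, 2, cumsum)
    if (d[1] == 1L) cum <- matrix(cum, nrow = 1L)
    for (r in seq_len(d[2])) {
      out[[length(out) + 1L]] <- data.frame(
        year = years, region = region_names[r], category = cats[k],
        cumulative = cum[, r])
    }
    out[[length(out) + 1L]] <- data.frame(
      year = years, region = "total", category = cats[k],
      cumulative = rowSums(cum))
  }
  do.call(rbind, out)
}

#' Yearly critical flags for one population region
#'
#' The published record does not state how a population-year is declared
#' critical, so two modes are provided. `"regional_mean_series"` computes
#' phenology on the region's area-weighted mean monthly SIC series and
#' classifies that single season per year. `"pixel_fraction"` computes
#' per-pixel seasons and triggers a category when the area fraction of
#' marine pixels whose own season is critical reaches
#' `pixel_fraction_cutoff`.
#'
#' @param fields an [ice_fieldset].
#' @param mask a [region_mask].
#' @param region_id region label to evaluate.
#' @param thresholds a [threshold_config()]; `region_event_mode` and
#'   `pixel_fraction_cutoff` select and tune the mode.
#' @param phen optional precomputed [phenology_fieldset()] result, used by
#'   `"pixel_fraction"` mode to avoid recomputation.
#' @return logical matrix `(year, category)` with columns `A`-`D`.
#' @export
region_year_critical <- function(fields, mask, region_id,
                                 thresholds = threshold_config(),
                                 phen = NULL) {
  stopifnot(inherits(fields, "ice_fieldset"), inherits(mask, "region_mask"))
  sel <- mask$labels == region_id & !fields$land_mask
  if (!any(sel)) stop("empty region", call. = FALSE)
  nyr <- n_years(fields)
  out <- matrix(NA, nyr, 4, dimnames = list(NULL, c("A", "B", "C", "D")))
  if (thresholds$region_event_mode == "regional_mean_series") {
    w <- mask$cell_area[sel]
    nt <- 12L * nyr
    flat <- matrix(fields$sic, nrow = nt)          # (time, pixel)
    series <- as.numeric(flat[, as.vector(sel), drop = FALSE] %*% w) / sum(w)
    for (k in seq_len(nyr)) {
      cur <- series[(k - 1L) * 12L + 1:12]
      nxt <- if (k < nyr) series[k * 12L + 1:12]
      ps <- ice_free_season(cur, nxt, thresholds, year = fields$years[k],
                            calendar = fields$calendar)
      out[k, ] <- classify_critical(ps, thresholds)
    }
  } else {
    if (is.null(phen)) phen <- phenology_fieldset(fields, thresholds)
    w <- mask$cell_area
    for (k in seq_len(nyr)) {
      ld <- phen$length_days[k, , ]
      bm <- phen$breakup_month[k, , ]
      valid <- sel & !is.na(ld)
      if (!any(valid)) next
      tot <- sum(w[valid])
      frac <- function(flag) sum(w[valid & flag]) / tot
      fA <- !is.na(ld) & ld >= thresholds$critical_a_days
      fB <- !is.na(ld) & ld >= thresholds$critical_b_days
      fC <- !is.na(bm) & bm <= thresholds$critical_c_month
      fD <- !is.na(bm) & bm <= thresholds$critical_d_month
      cut <- thresholds$pixel_fraction_cutoff
      out[k, ] <- c(frac(fA) >= cut, frac(fB) >= cut,
                    frac(fC) >= cut, frac(fD) >= cut)
    }
  }
  out
}
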