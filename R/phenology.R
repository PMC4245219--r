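#' Break-up month of a year of monthly SIC
#'
#' Break-up is the first month of the year whose mean SIC falls below the
#' break-up threshold (50%), the concentration at which bears move ashore
#' in seasonal-ice regions. The first qualifying month is reported even if
#' SIC later recovers; there is no re-break-up detection.
#'
#' @param sic_year numeric vector of 12 monthly SIC values (%).
#' @param thresholds a [threshold_config()].
#' @return month index 1-12, or `NA_integer_` if no month qualifies.
#' @export
#' @examples
#' breakup_month(c(100, 100, 95, 80, 45, 20, 5, 5, 20, 60, 90, 100))  # 5
breakup_month <- function(sic_year, thresholds = threshold_config()) {
  if (length(sic_year) != 12) stop("sic_year must have 12 months", call. = FALSE)
  hit <- which(sic_year < thresholds$sic_breakup_pct)
  if (length(hit) == 0) NA_integer_ else hit[1]
}

#' Ice-free season of one year
#'
#' The ice-free period runs from break-up (first month with SIC below 50%)
#' until freeze-up begins (SIC recovering to at least 10%). Freeze-up is
#' the first month at or after break-up whose SIC is at or above the
#' freeze-up threshold while the immediately preceding month was below it
#' (an upward crossing), searched up to 12 months past break-up, wrapping
#' into the following year when available. If SIC never drops below the
#' freeze-up threshold the season is zero months; if it drops but never
#' recovers within the horizon the season is capped at twelve months.
#' Day lengths use the calendar's true month lengths.
#'
#' @param sic_year numeric vector of 12 monthly SIC values (%).
#' @param sic_next_year optional 12 monthly values for the following year;
#'   omit for the last year of a record.
#' @param thresholds a [threshold_config()].
#' @param year calendar year of `sic_year` (used for leap days).
#' @param calendar `"standard"` or `"noleap"`.
#' @return list with `breakup_month` (1-12 or `NA`), `freezeup_month`
#'   (index from January of the season year, may exceed 12, or `NA`),
#'   `length_months` (0-12) and `length_days`; all `NA` when a needed month
#'   is missing.
#' @export
#' @examples
#' s <- c(100, 100, 90, 70, 40, 8, 5, 6, 15, 70, 95, 100)
#' ice_free_season(s)$length_months  # 4 (May through August)
ice_free_season <- function(sic_year, sic_next_year = NULL,
                            thresholds = threshold_config(),
                            year = 2000L, calendar = c("standard", "noleap")) {
  calendar <- match.arg(calendar)
  if (length(sic_year) != 12) stop("sic_year must have 12 months", call. = FALSE)
  if (!is.null(sic_next_year) && length(sic_next_year) != 12) {
    stop("sic_next_year must have 12 months", call. = FALSE)
  }
  na_season <- list(breakup_month = NA_integer_, freezeup_month = NA_integer_,
                    length_months = NA_integer_, length_days = NA_real_)
  if (anyNA(sic_year)) return(na_season)
  b <- breakup_month(sic_year, thresholds)
  zero <- list(breakup_month = b, freezeup_month = NA_integer_,
               length_months = 0L, length_days = 0)
  if (is.na(b)) return(zero)

  series <- c(sic_year, sic_next_year)      # 12 or 24 months from January
  fz <- thresholds$sic_freezeup_pct
  horizon <- min(b + 12L, length(series))   # last searchable month index
  search <- b:horizon
  if (anyNA(series[search])) return(na_season)

  below <- series[search] < fz
  if (!any(below)) return(zero)             # never drops below: no season
  # upward crossing: month >= fz with previous month < fz; the month before
  # b (unavailable at b = 1) can never certify a crossing
  f <- NA_integer_
  for (m in search) {
    if (m == 1L) next
    if (series[m] >= fz && series[m - 1L] < fz) { f <- m; break }
  }
  if (is.na(f)) f <- horizon + 1L           # no recovery: cap at horizon
  len <- min(f - b, 12L)
  f <- b + len
  mon <- b:(f - 1L)
  days <- sum(month_days(((mon - 1L) %% 12L) + 1L,
                         year + (mon - 1L) %/% 12L, calendar))
  list(breakup_month = b, freezeup_month = f,
       length_months = as.integer(len), length_days = days)
}

#' Per-pixel ice-free phenology of a field set
#'
#' Applies [ice_free_season()] to every marine pixel and year, using the
#' following year as look-ahead for the freeze-up search (the last year has
#' none).
#'
#' @param fields an [ice_fieldset].
#' @param thresholds a [threshold_config()].
#' @return object of class `ice_phenology`: list of `(year, y, x)` arrays
#'   `breakup_month`, `freezeup_month`, `length_months`, `length_days`,
#'   plus `years` and `calendar`.
#' @export
phenology_fieldset <- function(fields, thresholds = threshold_config()) {
  stopifnot(inherits(fields, "ice_fieldset"))
  nyr <- n_years(fields)
  dims <- c(nyr, fields$ny, fields$nx)
  out <- list(breakup_month = array(NA_integer_, dims),
              freezeup_month = array(NA_integer_, dims),
              length_months = array(NA_integer_, dims),
              length_days = array(NA_real_, dims),
              years = fields$years, calendar = fields$calendar)
  for (j in seq_len(fields$nx)) {
    for (i in seq_len(fields$ny)) {
      if (fields$land_mask[i, j]) next
      s <- fields$sic[, i, j]
      for (k in seq_len(nyr)) {
        cur <- s[(k - 1L) * 12L + 1:12]
        nxt <- if (k < nyr) s[k * 12L + 1:12]
        ps <- ice_free_season(cur, nxt, thresholds,
                              year = fields$years[k],
                              calendar = fields$calendar)
        out$breakup_month[k, i, j] <- ps$breakup_month
        out$freezeup_month[k, i, j] <- ps$freezeup_month
        out$length_months[k, i, j] <- ps$length_months
        out$length_days[k, i, j] <- ps$length_days
      }
    }
  }
  class(out) <- "ice_phenology"
  out
}

#' @export
print.ice_phenology <- function(x, ...) {
  cat(sprintf("<ice_phenology> %d years (%d-%d), %d x %d grid, %s calendar\n",
              length(x$years), min(x$years), max(x$years),
              dim(x$length_months)[2], dim(x$length_months)[3], x$calendar))
  cat(sprintf("  mean season length: %.2f months\n",
              mean(x$length_months, na.rm = TRUE)))
  invisible(x)
}
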