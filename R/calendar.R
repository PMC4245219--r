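#' Calendar-month lengths under a model calendar
#'
#' Climate-model output commonly uses a 365-day ("noleap") calendar; day
#' counts for ice-free-season lengths must honour the dataset's declared
#' calendar.
#'
#' @param months integer vector of calendar months (1-12).
#' @param years integer vector of calendar years, recycled against `months`.
#' @param calendar `"standard"` (proleptic Gregorian, with leap days) or
#'   `"noleap"` (fixed 365-day year).
#' @return integer vector of day counts per month.
#' @export
#' @examples
#' month_days(2, 2000)                       # 29
#' month_days(2, 2000, calendar = "noleap")  # 28
month_days <- function(months, years, calendar = c("standard", "noleap")) {
  calendar <- match.arg(calendar)
  stopifnot(all(months %in% 1:12))
  base <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)
  n <- max(length(months), length(years))
  months <- rep_len(as.integer(months), n)
  years <- rep_len(as.integer(years), n)
  d <- base[months]
  if (calendar == "standard") {
    leap <- (years %% 4 == 0 & years %% 100 != 0) | (years %% 400 == 0)
    d[months == 2L & leap] <- 29L
  }
  d
}
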