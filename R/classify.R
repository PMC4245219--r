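#' Ice-type codes
#'
#' Integer encoding used in class maps: 0 = missing, 1 = multiyear,
#' 2 = annual, 3 = ice_free.
#' @return named integer vector.
#' @export
ice_class_codes <- function() {
  c(missing = 0L, multiyear = 1L, annual = 2L, ice_free = 3L)
}

new_ice_class_map <- function(class_array, years) {
  stopifnot(is.array(class_array), length(dim(class_array)) == 3,
            dim(class_array)[1] == length(years))
  x <- list(class = class_array, years = as.integer(years))
  class(x) <- "ice_class_map"
  x
}

#' @export
print.ice_class_map <- function(x, ...) {
  cat(sprintf("<ice_class_map> %d years (%d-%d), %d x %d grid\n",
              length(x$years), min(x$years), max(x$years),
              dim(x$class)[2], dim(x$class)[3]))
  tab <- table(factor(x$class, levels = 0:3,
                      labels = names(ice_class_codes())))
  print(tab)
  invisible(x)
}

#' Classify one pixel-year as multiyear ice, annual ice, or ice-free
#'
#' A pixel-year is multiyear ice when SIC stays at or above the presence
#' threshold (15%) in every month. It is ice-free when SIC stays below the
#' threshold all year and ice was also absent throughout the prior twelve
#' months (or no prior year exists). Otherwise ice was present at some
#' point in the current or prior year but dipped below the threshold within
#' the year: annual ice. Any missing month in the current year makes the
#' pixel-year missing, since every rule quantifies over all 12 months.
#'
#' @param sic_year numeric vector of 12 monthly SIC values (%).
#' @param sic_prior_year optional 12 monthly values for the preceding year;
#'   omit for the first year of a record.
#' @param thresholds a [threshold_config()].
#' @return one of `"multiyear"`, `"annual"`, `"ice_free"`, `"missing"`.
#' @export
#' @examples
#' classify_pixel_year(rep(50, 12))                    # "multiyear"
#' classify_pixel_year(rep(5, 12), rep(40, 12))        # "annual"
#' classify_pixel_year(rep(5, 12), rep(5, 12))         # "ice_free"
classify_pixel_year <- function(sic_year, sic_prior_year = NULL,
                                thresholds = threshold_config()) {
  if (length(sic_year) != 12) stop("sic_year must have 12 months", call. = FALSE)
  if (!is.null(sic_prior_year) && length(sic_prior_year) != 12) {
    stop("sic_prior_year must have 12 months", call. = FALSE)
  }
  if (anyNA(sic_year)) return("missing")
  if (any(sic_year < 0 | sic_year > 100)) {
    stop("SIC outside [0, 100]", call. = FALSE)
  }
  thr <- thresholds$sic_presence_pct
  if (min(sic_year) >= thr) return("multiyear")
  if (max(sic_year) < thr) {
    # ice absent all year; ice-free only if also absent throughout the
    # prior year (look-back skipped when no prior year exists)
    prior_max <- if (is.null(sic_prior_year) || all(is.na(sic_prior_year))) {
      -Inf
    } else {
      max(sic_prior_year, na.rm = TRUE)
    }
    if (prior_max < thr) return("ice_free")
  }
  "annual"
}

#' Classify every marine pixel-year of a field set
#'
#' Applies [classify_pixel_year()] per pixel with a 12-month look-back
#' (previous calendar year) for the annual-ice clause; the first year of
#' record has no look-back. Land pixels and pixel-years with any missing
#' month are coded missing.
#'
#' @param fields an [ice_fieldset].
#' @param thresholds a [threshold_config()].
#' @return an `ice_class_map` with an integer `(year, y, x)` class array,
#'   encoded per [ice_class_codes()].
#' @export
classify_fieldset <- function(fields, thresholds = threshold_config()) {
  stopifnot(inherits(fields, "ice_fieldset"))
  nyr <- n_years(fields)
  thr <- thresholds$sic_presence_pct
  codes <- ice_class_codes()
  cls <- array(codes[["missing"]], dim = c(nyr, fields$ny, fields$nx))
  prior_max <- NULL
  for (k in seq_len(nyr)) {
    slab <- fields$sic[(k - 1L) * 12L + 1:12, , , drop = FALSE]
    cur_min <- apply(slab, c(2, 3), min)   # NA when any month missing
    # look-back max uses available months only (-Inf when none), matching
    # classify_pixel_year's handling of partially missing prior years
    cur_max <- apply(slab, c(2, 3), function(v) {
      if (all(is.na(v))) -Inf else max(v, na.rm = TRUE)
    })
    ok <- !is.na(cur_min)
    multi <- ok & cur_min >= thr
    free <- ok & cur_max < thr &
      (if (is.null(prior_max)) TRUE else prior_max < thr)
    layer <- matrix(codes[["missing"]], fields$ny, fields$nx)
    layer[ok] <- codes[["annual"]]
    layer[multi] <- codes[["multiyear"]]
    layer[free] <- codes[["ice_free"]]
    cls[k, , ] <- layer
    prior_max <- cur_max
  }
  new_ice_class_map(cls, fields$years)
}
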