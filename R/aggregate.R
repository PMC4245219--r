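#' Regional monthly climatologies over named periods
#'
#' For each region, period and calendar month, the area-weighted mean of
#' SIC (and thickness and snow when present) over the region's marine
#' pixels and the period's years — the numbers behind period-comparison
#' seasonal-cycle panels. Default periods compare the recent past
#' (1992-2005) with the near future (2040-2050) and late century
#' (2080-2090).
#'
#' @param fields an [ice_fieldset].
#' @param mask a [region_mask].
#' @param periods list of `c(start, end)` year pairs.
#' @return tidy `data.frame`: `region`, `period`, `month`, `variable`,
#'   `value`.
#' @export
period_climatology <- function(fields, mask,
                               periods = list(c(1992, 2005), c(2040, 2050),
                                              c(2080, 2090))) {
  stopifnot(inherits(fields, "ice_fieldset"), inherits(mask, "region_mask"))
  ids <- sort(unique(mask$labels[mask$labels > 0L]))
  vars <- c("sic",
            if (!is.null(fields$thickness)) "thickness",
            if (!is.null(fields$snow)) "snow")
  rows <- list()
  for (p in periods) {
    if (p[1] < min(fields$years) || p[2] > max(fields$years)) {
      stop(sprintf("period %d-%d outside record %d-%d", p[1], p[2],
                   min(fields$years), max(fields$years)), call. = FALSE)
    }
    ky <- which(fields$years >= p[1] & fields$years <= p[2])
    pname <- sprintf("%d-%d", p[1], p[2])
    for (id in ids) {
      sel <- mask$labels == id & !fields$land_mask
      if (!any(sel)) stop(sprintf("region %d empty", id), call. = FALSE)
      w <- mask$cell_area[sel]
      for (v in vars) {
        flat <- matrix(fields[[v]], nrow = 12L * n_years(fields))
        sub <- flat[, as.vector(sel), drop = FALSE]
        for (m in 1:12) {
          tt <- (ky - 1L) * 12L + m
          vals <- sub[tt, , drop = FALSE]
          wm <- rep(w, each = length(tt))
          ok <- !is.na(vals)
          rows[[length(rows) + 1L]] <- data.frame(
            region = mask$names[id], period = pname, month = m, variable = v,
            value = if (any(ok)) sum(vals[ok] * wm[ok]) / sum(wm[ok]) else NA_real_)
        }
      }
    }
  }
  do.call(rbind, rows)
}

#' Yearly ice-type area proportions by region
#'
#' Area-weighted fractions of each region classified multiyear, annual and
#' ice-free, over non-missing pixels, plus an all-region `"total"` row per
#' year. Fractions sum to one over the classified area; a region-year with
#' no classified pixels yields `NA` fractions.
#'
#' @param classes an `ice_class_map` from [classify_fieldset()].
#' @param mask a [region_mask].
#' @return `data.frame`: `year`, `region`, `multiyear`, `annual`,
#'   `ice_free`, `classified_area`.
#' @export
ice_type_proportions <- function(classes, mask) {
  stopifnot(inherits(classes, "ice_class_map"), inherits(mask, "region_mask"))
  codes <- ice_class_codes()
  ids <- sort(unique(mask$labels[mask$labels > 0L]))
  rows <- list()
  prop_row <- function(cl, sel, w, year, name) {
    ww <- w * sel
    denom <- sum(ww[cl != codes[["missing"]]])
    f <- function(code) {
      if (denom == 0) NA_real_ else sum(ww[cl == code]) / denom
    }
    data.frame(year = year, region = name,
               multiyear = f(codes[["multiyear"]]),
               annual = f(codes[["annual"]]),
               ice_free = f(codes[["ice_free"]]),
               classified_area = denom)
  }
  for (k in seq_along(classes$years)) {
    cl <- classes$class[k, , ]
    for (id in ids) {
      rows[[length(rows) + 1L]] <- prop_row(
        cl, mask$labels == id, mask$cell_area, classes$years[k],
        mask$names[id])
    }
    rows[[length(rows) + 1L]] <- prop_row(
      cl, mask$labels > 0L, mask$cell_area, classes$years[k], "total")
  }
  do.call(rbind, rows)
}

#' Yearly ringed-seal snow-habitat flag by region
#'
#' A region-year supports seal lairs when its area-weighted mean snow depth
#' over ice-covered pixels (SIC at or above the presence threshold) in the
#' assessment month reaches the minimum snow depth (default 20 cm, i.e.
#' 0.2 m). A region with no ice-covered pixels that month is flagged
#' `FALSE` with a warning.
#'
#' @param fields an [ice_fieldset] with a `snow` variable.
#' @param mask a [region_mask].
#' @param thresholds a [threshold_config()]; `snow_month` sets the
#'   assessment month (default April) and `seal_snow_cm` the depth.
#' @return `data.frame`: `year`, `region`, `mean_snow_cm`, `seal_habitat`.
#' @export
seal_habitat_flag <- function(fields, mask, thresholds = threshold_config()) {
  stopifnot(inherits(fields, "ice_fieldset"))
  if (is.null(fields$snow)) stop("field set has no snow variable", call. = FALSE)
  ids <- sort(unique(mask$labels[mask$labels > 0L]))
  rows <- list()
  for (k in seq_len(n_years(fields))) {
    tt <- (k - 1L) * 12L + thresholds$snow_month
    sic_m <- fields$sic[tt, , ]
    snow_m <- fields$snow[tt, , ]
    for (id in ids) {
      sel <- mask$labels == id & !fields$land_mask &
        !is.na(sic_m) & sic_m >= thresholds$sic_presence_pct & !is.na(snow_m)
      if (!any(sel)) {
        warning(sprintf("region %s has no ice-covered pixels in year %d",
                        mask$names[id], fields$years[k]), call. = FALSE)
        mean_cm <- NA_real_
        flag <- FALSE
      } else {
        w <- mask$cell_area[sel]
        mean_cm <- 100 * sum(snow_m[sel] * w) / sum(w)
        flag <- mean_cm >= thresholds$seal_snow_cm
      }
      rows[[length(rows) + 1L]] <- data.frame(
        year = fields$years[k], region = mask$names[id],
        mean_snow_cm = mean_cm, seal_habitat = flag)
    }
  }
  do.call(rbind, rows)
}

#' Fraction of study area breaking up by a given month
#'
#' The yearly area-weighted fraction of the study area's marine pixels
#' whose break-up month falls at or before `month` — the quantity behind
#' statements like "over 80% of the archipelago experiences July
#' break-up". Pixels with a missing season are excluded from the
#' denominator; pixels that never break up count as not broken up.
#'
#' @param phen an `ice_phenology` from [phenology_fieldset()].
#' @param mask a [region_mask].
#' @param month latest qualifying break-up month (default July).
#' @return `data.frame`: `year`, `fraction` in `[0, 1]`.
#' @export
breakup_area_fraction <- function(phen, mask, month = 7) {
  stopifnot(inherits(phen, "ice_phenology"), inherits(mask, "region_mask"))
  in_area <- mask$labels > 0L
  rows <- lapply(seq_along(phen$years), function(k) {
    lm <- phen$length_months[k, , ]
    bm <- phen$breakup_month[k, , ]
    valid <- in_area & !is.na(lm)
    denom <- sum(mask$cell_area[valid])
    hit <- valid & !is.na(bm) & bm <= month
    data.frame(year = phen$years[k],
               fraction = if (denom == 0) NA_real_
                          else sum(mask$cell_area[hit]) / denom)
  })
  do.call(rbind, rows)
}
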