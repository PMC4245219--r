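#' Gridded monthly ice field set
#'
#' The pipeline's universal input: monthly-mean sea-ice concentration (SIC,
#' percent), and optionally ice thickness and snow depth (metres), on a 2-D
#' grid over whole calendar years. Land pixels carry `NA`, never 0.
#'
#' @param sic numeric array `(time, y, x)` of monthly-mean SIC in percent
#'   `[0, 100]`; the time dimension must be a multiple of 12 (whole years,
#'   January to December).
#' @param start_year calendar year of the first time step.
#' @param thickness optional array, same shape, ice thickness in metres
#'   (non-negative).
#' @param snow optional array, same shape, snow depth on ice in metres
#'   (non-negative).
#' @param land_mask logical matrix `(y, x)`; `TRUE` marks land.
#' @param calendar `"standard"` or `"noleap"`; used for day counts.
#'
#' @return Object of class `ice_fieldset` with elements `sic`, `thickness`,
#'   `snow`, `land_mask`, `years`, `calendar` and grid dims `ny`, `nx`.
#' @export
ice_fieldset <- function(sic, start_year, thickness = NULL, snow = NULL,
                         land_mask = NULL, calendar = c("standard", "noleap")) {
  calendar <- match.arg(calendar)
  stopifnot(is.array(sic), length(dim(sic)) == 3)
  nt <- dim(sic)[1]
  if (nt == 0 || nt %% 12 != 0) {
    stop("time axis must hold whole years: incomplete final year", call. = FALSE)
  }
  ny <- dim(sic)[2]; nx <- dim(sic)[3]
  if (is.null(land_mask)) land_mask <- matrix(FALSE, ny, nx)
  stopifnot(is.matrix(land_mask), all(dim(land_mask) == c(ny, nx)))
  # land pixels hold NA throughout; enforce at construction
  if (any(land_mask)) {
    mask3 <- aperm(array(land_mask, c(ny, nx, nt)), c(3, 1, 2))
    sic[mask3] <- NA_real_
    if (!is.null(thickness)) thickness[mask3] <- NA_real_
    if (!is.null(snow)) snow[mask3] <- NA_real_
  }
  rng <- suppressWarnings(range(sic, na.rm = TRUE))
  if (is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 100)) {
    stop("SIC outside [0, 100] percent", call. = FALSE)
  }
  for (v in list(thickness, snow)) {
    if (!is.null(v)) {
      stopifnot(all(dim(v) == dim(sic)))
      if (isTRUE(min(v, na.rm = TRUE) < 0)) {
        stop("thickness/snow must be non-negative", call. = FALSE)
      }
    }
  }
  fs <- list(
    sic = sic, thickness = thickness, snow = snow,
    land_mask = land_mask,
    years = seq.int(start_year, length.out = nt %/% 12),
    calendar = calendar, ny = ny, nx = nx
  )
  class(fs) <- "ice_fieldset"
  fs
}

#' @export
print.ice_fieldset <- function(x, ...) {
  cat(sprintf(
    "<ice_fieldset> %d x %d grid, years %d-%d (%s calendar)\n",
    x$ny, x$nx, min(x$years), max(x$years), x$calendar))
  cat(sprintf("  variables: sic%s%s; land pixels: %d\n",
              if (!is.null(x$thickness)) ", thickness" else "",
              if (!is.null(x$snow)) ", snow" else "",
              sum(x$land_mask)))
  invisible(x)
}

#' Number of years in a field set
#' @param fields an `ice_fieldset`.
#' @return integer year count.
#' @export
n_years <- function(fields) length(fields$years)

#' Extract one pixel's monthly SIC series
#' @param fields an `ice_fieldset`.
#' @param i,j grid row (y) and column (x).
#' @return numeric vector, length `12 * n_years(fields)`.
#' @export
pixel_series <- function(fields, i, j) as.numeric(fields$sic[, i, j])

#' Population region mask
#'
#' Integer region labels on the grid (0 = outside the study area), a name
#' per region, and per-pixel cell areas for area weighting. The seven
#' default names are the polar bear management units of the Canadian Arctic
#' Archipelago.
#'
#' @param labels integer matrix `(y, x)`; 0 outside the study area,
#'   1..k inside. Land pixels must be 0.
#' @param names character vector naming regions 1..k.
#' @param cell_area numeric matrix `(y, x)` of per-pixel areas (km^2),
#'   strictly positive; defaults to 1 everywhere (equal weighting).
#' @return Object of class `region_mask`.
#' @export
region_mask <- function(labels, names, cell_area = NULL) {
  stopifnot(is.matrix(labels))
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  ids <- sort(unique(labels[labels > 0L]))
  if (length(ids) && max(ids) > length(names)) {
    stop("every nonzero region label needs a name", call. = FALSE)
  }
  if (is.null(cell_area)) cell_area <- matrix(1, nrow(labels), ncol(labels))
  stopifnot(all(dim(cell_area) == dim(labels)))
  if (any(cell_area <= 0)) stop("cell_area must be positive", call. = FALSE)
  m <- list(labels = labels, names = as.character(names), cell_area = cell_area)
  class(m) <- "region_mask"
  m
}

#' @export
print.region_mask <- function(x, ...) {
  ids <- sort(unique(x$labels[x$labels > 0L]))
  cat(sprintf("<region_mask> %d x %d grid, %d regions\n",
              nrow(x$labels), ncol(x$labels), length(ids)))
  for (id in ids) {
    cat(sprintf("  %d %-18s %d pixels\n", id, x$names[id],
                sum(x$labels == id)))
  }
  invisible(x)
}

#' Default region names: the seven CAA polar bear populations
#' @return character vector of length 7.
#' @export
caa_region_names <- function() {
  c("Kane Basin", "Norwegian Bay", "Queen Elizabeth", "Lancaster Sound",
    "Viscount Melville", "M'Clintock Channel", "Gulf of Boothia")
}
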