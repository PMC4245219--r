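#' Write a gridded field set to disk
#'
#' Serializes an [ice_fieldset] as a pair of plain-text files: a JSON header
#' carrying the CF-style metadata (grid shape, time axis, calendar, units,
#' land mask) and a delimited long table of the field values with explicit
#' `year, month, y, x` coordinates. Integers round-trip bit-exactly; floats
#' to the declared precision.
#'
#' @param fields an [ice_fieldset].
#' @param stem output path stem; `<stem>.json` and `<stem>.csv` are written.
#' @param digits significant digits retained for float fields.
#' @return `stem`, invisibly.
#' @export
write_fieldset <- function(fields, stem, digits = 7) {
  stopifnot(inherits(fields, "ice_fieldset"))
  vars <- c("sic",
            if (!is.null(fields$thickness)) "thickness",
            if (!is.null(fields$snow)) "snow")
  header <- list(
    format = "icefree-fieldset", version = 1L,
    ny = fields$ny, nx = fields$nx,
    start_year = min(fields$years), n_years = length(fields$years),
    calendar = fields$calendar,
    variables = vars,
    units = as.list(c(sic = "percent", thickness = "m", snow = "m")[vars]),
    land_mask = as.integer(fields$land_mask)  # column-major (y fastest)
  )
  jsonlite::write_json(header, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  nt <- 12L * length(fields$years)
  grid <- expand.grid(t = seq_len(nt), y = seq_len(fields$ny),
                      x = seq_len(fields$nx))
  dt <- data.table::data.table(
    year = fields$years[(grid$t - 1L) %/% 12L + 1L],
    month = (grid$t - 1L) %% 12L + 1L,
    y = grid$y, x = grid$x
  )
  for (v in vars) dt[[v]] <- signif(as.numeric(fields[[v]]), digits)
  data.table::fwrite(dt, paste0(stem, ".csv"))
  invisible(stem)
}

#' Read a gridded field set
#'
#' Inverse of [write_fieldset()], with boundary-unit handling: SIC stored as
#' a fraction in `[0, 1]` (declared by a `units` entry of `"1"` or
#' `"fraction"`, or detected by a maximum at or below 1.5 when no unit is
#' declared) is converted to percent exactly once. The time axis is
#' validated as consecutive calendar months covering whole years.
#'
#' @param stem path stem used at write time (or the `.json` header path).
#' @return an [ice_fieldset] with SIC in percent.
#' @export
read_fieldset <- function(stem) {
  stem <- sub("\\.json$", "", stem)
  header <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  dt <- data.table::fread(paste0(stem, ".csv"))
  if (!"sic" %in% names(dt)) stop("missing SIC variable", call. = FALSE)
  data.table::setorder(dt, x, y, year, month)
  ny <- header$ny; nx <- header$nx
  tkey <- unique(dt[, c("year", "month")])
  data.table::setorder(tkey, year, month)
  nt <- nrow(tkey)
  step <- tkey$year * 12L + tkey$month
  if (nt < 2 || any(diff(step) != 1L)) {
    stop("time axis is not consecutive monthly", call. = FALSE)
  }
  if (nt %% 12L != 0L || tkey$month[1] != 1L) {
    stop("incomplete final year: time axis must hold whole Jan-Dec years",
         call. = FALSE)
  }
  if (nrow(dt) != nt * ny * nx) stop("grid/time table is gapped", call. = FALSE)
  to_array <- function(v) array(v, dim = c(nt, ny, nx))
  sic <- to_array(dt$sic)
  sic <- convert_sic_units(sic, header$units[["sic"]])
  thickness <- if ("thickness" %in% names(dt)) to_array(dt$thickness)
  snow <- if ("snow" %in% names(dt)) to_array(dt$snow)
  land <- matrix(as.logical(header$land_mask), ny, nx)
  ice_fieldset(sic, start_year = tkey$year[1], thickness = thickness,
               snow = snow, land_mask = land, calendar = header$calendar)
}

# percent is canonical internally; fractions are converted at this boundary
# and never twice (percent data with max > 1.5 passes through unchanged).
convert_sic_units <- function(sic, units) {
  mx <- suppressWarnings(max(sic, na.rm = TRUE))
  if (is.null(units) || is.na(units) || units == "") {
    if (!is.finite(mx)) stop("SIC units undeterminable: no data", call. = FALSE)
    if (mx <= 1.5) sic <- sic * 100
    return(sic)
  }
  if (units %in% c("percent", "%")) return(sic)
  if (units %in% c("1", "fraction")) return(sic * 100)
  stop(sprintf("SIC units undeterminable: '%s'", units), call. = FALSE)
}

#' Write a region mask
#' @param mask a [region_mask].
#' @param stem output path stem; `<stem>.json` and `<stem>.csv` are written.
#' @return `stem`, invisibly.
#' @export
write_region_mask <- function(mask, stem) {
  stopifnot(inherits(mask, "region_mask"))
  header <- list(format = "icefree-regionmask", version = 1L,
                 ny = nrow(mask$labels), nx = ncol(mask$labels),
                 names = mask$names)
  jsonlite::write_json(header, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  grid <- expand.grid(y = seq_len(nrow(mask$labels)),
                      x = seq_len(ncol(mask$labels)))
  dt <- data.table::data.table(y = grid$y, x = grid$x,
                               region = as.integer(mask$labels),
                               cell_area = as.numeric(mask$cell_area))
  data.table::fwrite(dt, paste0(stem, ".csv"))
  invisible(stem)
}

#' Read a region mask written by [write_region_mask()]
#' @param stem path stem.
#' @return a [region_mask].
#' @export
read_region_mask <- function(stem) {
  stem <- sub("\\.json$", "", stem)
  header <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  dt <- data.table::fread(paste0(stem, ".csv"))
  data.table::setorder(dt, x, y)
  region_mask(matrix(dt$region, header$ny, header$nx),
              names = header$names,
              cell_area = matrix(dt$cell_area, header$ny, header$nx))
}

#' Write a stage output to disk
#'
#' Tables (data frames) are written as tab-delimited text with a header row;
#' per-pixel class maps as a JSON header plus an integer long table that
#' round-trips exactly.
#'
#' @param x a stage output: `data.frame` or `ice_class_map`.
#' @param path output file path (stem for class maps).
#' @return `path`, invisibly.
#' @export
write_results <- function(x, path) UseMethod("write_results")

#' @export
write_results.data.frame <- function(x, path) {
  data.table::fwrite(x, path, sep = "\t")
  invisible(path)
}

#' @export
write_results.ice_class_map <- function(x, path) {
  stem <- sub("\\.json$", "", path)
  header <- list(format = "icefree-classmap", version = 1L,
                 ny = dim(x$class)[2], nx = dim(x$class)[3],
                 years = x$years,
                 encoding = c(missing = 0L, multiyear = 1L, annual = 2L,
                              ice_free = 3L))
  jsonlite::write_json(header, paste0(stem, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  grid <- expand.grid(year = x$years, y = seq_len(dim(x$class)[2]),
                      x = seq_len(dim(x$class)[3]))
  dt <- data.table::data.table(year = grid$year, y = grid$y, x = grid$x,
                               class = as.integer(x$class))
  data.table::fwrite(dt, paste0(stem, ".csv"))
  invisible(path)
}

#' Read a class map written by [write_results()]
#' @param stem path stem.
#' @return an `ice_class_map`.
#' @export
read_classmap <- function(stem) {
  stem <- sub("\\.json$", "", stem)
  header <- jsonlite::read_json(paste0(stem, ".json"), simplifyVector = TRUE)
  dt <- data.table::fread(paste0(stem, ".csv"))
  data.table::setorder(dt, x, y, year)
  cls <- array(as.integer(dt$class),
               dim = c(length(header$years), header$ny, header$nx))
  new_ice_class_map(cls, header$years)
}
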