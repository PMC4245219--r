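#' Sub-monthly forcing series
#'
#' Light container for a sub-monthly (e.g. 3-hourly or daily) atmospheric
#' forcing field on a 2-D grid: a `(step, y, x)` value array with a
#' calendar year and month per step.
#'
#' @param values numeric array `(step, y, x)`.
#' @param year,month integer vectors, one entry per step.
#' @param variable variable name.
#' @return object of class `forcing_series`.
#' @export
forcing_series <- function(values, year, month, variable = "var") {
  stopifnot(is.array(values), length(dim(values)) == 3,
            dim(values)[1] == length(year), length(year) == length(month),
            all(month %in% 1:12))
  x <- list(values = values, year = as.integer(year),
            month = as.integer(month), variable = variable)
  class(x) <- "forcing_series"
  x
}

#' Monthly bias of a model forcing field against a reference
#'
#' For each calendar month, the bias layer is the difference (reference
#' minus model) or ratio (reference over model) of the two fields' monthly
#' means, where each monthly mean pools all sub-monthly steps of that
#' calendar month across the bias-window years (default 2005-2011, seven
#' years chosen to smooth the splice between reanalysis-driven and
#' model-driven forcing in a fast-trending climate). Ratio denominators
#' are guarded below by `eps` and the ratio capped at `max_ratio`, since
#' near-zero monthly means (summer precipitation and the like) are
#' otherwise unstable.
#'
#' @param model,reference [forcing_series] on the same grid, both covering
#'   the window.
#' @param window `c(start, end)` years of the bias window.
#' @param method `"difference"` or `"ratio"`.
#' @param eps ratio denominator floor, in the variable's units.
#' @param max_ratio cap on ratio biases.
#' @return object of class `bias_field`: 12 monthly `(y, x)` bias layers
#'   plus the method and window.
#' @export
compute_monthly_bias <- function(model, reference, window = c(2005, 2011),
                                 method = c("difference", "ratio"),
                                 eps = 1e-6, max_ratio = 10) {
  method <- match.arg(method)
  stopifnot(inherits(model, "forcing_series"),
            inherits(reference, "forcing_series"))
  if (!all(dim(model$values)[2:3] == dim(reference$values)[2:3])) {
    stop("grid mismatch between model and reference", call. = FALSE)
  }
  for (fs in list(model, reference)) {
    if (!all(window[1]:window[2] %in% fs$year)) {
      stop(sprintf("bias window %d-%d not covered by the series",
                   window[1], window[2]), call. = FALSE)
    }
  }
  ny <- dim(model$values)[2]; nx <- dim(model$values)[3]
  monthly_mean <- function(fs, m) {
    keep <- fs$month == m & fs$year >= window[1] & fs$year <= window[2]
    if (!any(keep)) {
      stop(sprintf("bias window %d-%d not covered for month %d",
                   window[1], window[2], m), call. = FALSE)
    }
    lay <- fs$values[keep, , , drop = FALSE]
    apply(lay, c(2, 3), mean)
  }
  layers <- array(NA_real_, c(12, ny, nx))
  for (m in 1:12) {
    mm <- monthly_mean(model, m)
    mr <- monthly_mean(reference, m)
    layers[m, , ] <- if (method == "difference") {
      mr - mm
    } else {
      pmin(mr / pmax(mm, eps), max_ratio)
    }
  }
  out <- list(variable = model$variable, method = method, window = window,
              layers = layers)
  class(out) <- "bias_field"
  out
}

#' Apply a monthly bias field to a sub-monthly series
#'
#' Every sub-monthly step in calendar month `m` receives that month's bias
#' as a step function: added for the difference method, multiplied for the
#' ratio method. Over the bias window the corrected monthly means then
#' match the reference's monthly means (exactly for differences, to float
#' precision for ratios away from the denominator guard).
#'
#' @param model a [forcing_series].
#' @param bias a `bias_field` from [compute_monthly_bias()].
#' @return corrected [forcing_series].
#' @export
apply_bias <- function(model, bias) {
  stopifnot(inherits(model, "forcing_series"), inherits(bias, "bias_field"))
  if (!all(dim(model$values)[2:3] == dim(bias$layers)[2:3])) {
    stop("grid mismatch between model and bias field", call. = FALSE)
  }
  out <- model
  for (m in 1:12) {
    idx <- which(model$month == m)
    if (!length(idx)) next
    lay <- bias$layers[m, , ]
    for (t in idx) {
      out$values[t, , ] <- if (bias$method == "difference") {
        model$values[t, , ] + lay
      } else {
        model$values[t, , ] * lay
      }
    }
  }
  out
}
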