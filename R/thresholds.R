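#' Threshold configuration for the sea-ice habitat pipeline
#'
#' Bundles every numeric threshold used by the classification, phenology,
#' critical-event and seal-habitat stages. Defaults follow the published
#' habitat rules: ice presence at 15% SIC, break-up below 50% SIC, freeze-up
#' recovery to 10% SIC, starvation-relevant season lengths of 120 and 180
#' days, reproductive-failure break-up months of July and June, and a 20 cm
#' minimum snow depth for ringed-seal habitat.
#'
#' @param sic_presence_pct SIC (%) at or above which ice counts as present;
#'   the multiyear / ice-free class boundary.
#' @param sic_breakup_pct SIC (%) below which a month counts as broken up.
#' @param sic_freezeup_pct SIC (%) at or above which freeze-up has begun.
#' @param critical_a_days minimum ice-free-season length (days) triggering
#'   category A (onset of starvation in adult males).
#' @param critical_b_days minimum length (days) for category B; must exceed
#'   `critical_a_days` so severities nest.
#' @param critical_c_month latest break-up month (1-12) triggering category C
#'   (reproductive failure risk); default July.
#' @param critical_d_month latest break-up month for the more severe
#'   category D; default June; must precede `critical_c_month`.
#' @param seal_snow_cm minimum snow depth (cm) on ice for viable ringed-seal
#'   lairs.
#' @param region_event_mode how a population-region-year is declared
#'   critical: `"regional_mean_series"` (phenology of the area-weighted mean
#'   SIC series) or `"pixel_fraction"` (fraction of marine area whose own
#'   season is critical).
#' @param pixel_fraction_cutoff area fraction in (0, 1] at or above which
#'   `"pixel_fraction"` mode triggers.
#' @param snow_month calendar month (1-12) in which the seal-habitat snow
#'   criterion is evaluated; default April, near the climatological maximum.
#'
#' @return An object of class `threshold_config`.
#' @export
#' @examples
#' cfg <- threshold_config()
#' cfg$sic_breakup_pct
threshold_config <- function(sic_presence_pct = 15,
                             sic_breakup_pct = 50,
                             sic_freezeup_pct = 10,
                             critical_a_days = 120,
                             critical_b_days = 180,
                             critical_c_month = 7,
                             critical_d_month = 6,
                             seal_snow_cm = 20,
                             region_event_mode = c("regional_mean_series",
                                                   "pixel_fraction"),
                             pixel_fraction_cutoff = 0.5,
                             snow_month = 4) {
  region_event_mode <- match.arg(region_event_mode)
  cfg <- list(
    sic_presence_pct = sic_presence_pct,
    sic_breakup_pct = sic_breakup_pct,
    sic_freezeup_pct = sic_freezeup_pct,
    critical_a_days = critical_a_days,
    critical_b_days = critical_b_days,
    critical_c_month = critical_c_month,
    critical_d_month = critical_d_month,
    seal_snow_cm = seal_snow_cm,
    region_event_mode = region_event_mode,
    pixel_fraction_cutoff = pixel_fraction_cutoff,
    snow_month = snow_month
  )
  class(cfg) <- "threshold_config"
  validate_threshold_config(cfg)
  cfg
}

#' @export
print.threshold_config <- function(x, ...) {
  cat("<threshold_config>\n")
  for (nm in names(x)) cat(sprintf("  %-22s %s\n", nm, format(x[[nm]])))
  invisible(x)
}

validate_threshold_config <- function(cfg) {
  stopifnot(inherits(cfg, "threshold_config"))
  if (!(cfg$sic_freezeup_pct > 0 &&
        cfg$sic_freezeup_pct < cfg$sic_breakup_pct &&
        cfg$sic_breakup_pct <= 100)) {
    stop("thresholds must satisfy 0 < freeze-up < break-up <= 100", call. = FALSE)
  }
  if (cfg$critical_b_days <= cfg$critical_a_days) {
    stop("critical_b_days must exceed critical_a_days", call. = FALSE)
  }
  if (cfg$critical_d_month >= cfg$critical_c_month) {
    stop("critical_d_month must precede critical_c_month", call. = FALSE)
  }
  if (!(cfg$pixel_fraction_cutoff > 0 && cfg$pixel_fraction_cutoff <= 1)) {
    stop("pixel_fraction_cutoff must lie in (0, 1]", call. = FALSE)
  }
  if (!(cfg$snow_month %in% 1:12) || !(cfg$critical_c_month %in% 1:12)) {
    stop("months must be integers in 1..12", call. = FALSE)
  }
  invisible(cfg)
}
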