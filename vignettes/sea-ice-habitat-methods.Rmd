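---
title: "Sea-ice habitat phenology for polar bear populations: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sea-ice habitat phenology for polar bear populations: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(icefree)
```

## The problem

Polar bears hunt from sea ice; when ice concentration falls too low for
too long they fast ashore, and energetics models tie fasting duration and
break-up timing to starvation and reproductive failure. This package
implements the habitat-side analysis chain for gridded monthly
sea-ice projections of the Canadian Arctic Archipelago (CAA): per-pixel
ice-type classification, ice-free-season phenology, critical-event and
point-of-no-return detection, region-level aggregation over the seven CAA
polar bear management units, and monthly-scale bias correction of forcing
fields. A seeded synthetic scenario generator stands in for the (not
publicly deposited) downscaled projection so that every stage is testable
end to end.

## Rules and thresholds

All thresholds live in one configuration object, `threshold_config()`,
with these defaults:

* **Ice presence, 15% SIC.** A pixel-year is *multiyear ice* when monthly
  SIC is at or above 15% in all twelve months; *ice-free* when below 15%
  in all twelve months of the current year and throughout the prior
  twelve months (the look-back is skipped in the first year of a record);
  otherwise *annual ice* — ice was present at 15%+ at some point in the
  current or prior year but melted out within the year.
* **Break-up, 50% SIC.** The first month of the calendar year with mean
  SIC below 50%, the concentration range in which bears abandon the ice.
  Only the first qualifying month is scored; there is no re-break-up.
* **Freeze-up, 10% SIC.** The ice-free season runs from break-up until
  SIC *recovers to* at least 10%: the first month at or after break-up
  with SIC ≥ 10% whose immediately preceding month was below 10%. The
  upward-crossing requirement is deliberate. A naive "first month ≥ 10%
  after break-up" would end the season in the break-up month itself
  whenever 10% ≤ SIC < 50%, contradicting the definitional edge case
  that a year never dipping below 10% has a *zero-month* season. The
  other printed edge case — all twelve months below 10% gives a
  *twelve-month* season — also holds by construction: the search for a
  recovery extends up to twelve months past break-up (wrapping into the
  following year when one exists) and the length is capped at twelve.
* **Critical categories.** A: season ≥ 120 days (starvation begins among
  adult males); B: ≥ 180 days (more severe); C: break-up by July
  (female reproductive failure risk); D: break-up by June. Day thresholds
  compare with ≥ and month thresholds with ≤, so an earlier break-up —
  strictly worse for bears — stays critical and severities nest
  (B ⇒ A, D ⇒ C).
* **Seal habitat, 20 cm snow.** A region-year supports ringed-seal lairs
  when the area-weighted mean snow depth over ice-covered pixels
  (SIC ≥ 15%) in the assessment month reaches 20 cm. The assessment month
  defaults to April — near the climatological snow maximum, before
  melt — and is configurable, since the source rule names a depth but not
  a date.

The *point of no return* for a category is the first year from which the
category is triggered in every remaining year of the record; if the final
year is not critical there is none. This makes the quantity
record-length-dependent by definition — a caveat worth remembering when
comparing runs of different lengths.

## Calendars and day counts

Season lengths are reported both in months and in days, because the
critical-day thresholds (120/180) are finer than the monthly resolution
of the data. Days are summed over the calendar months `[break-up,
freeze-up)` using the data set's declared calendar — `"standard"`
(Gregorian, with leap days) or `"noleap"` (fixed 365-day year, common in
climate-model output). A May-through-August season is 123 days in either
calendar; a full ice-free year is 365 or 366. No sub-monthly
interpolation is attempted: the rules are defined on monthly means.

## Declaring a population-year critical

The source record reports per-population critical events without stating
how a region-year is declared critical, so two modes are provided and the
choice is exposed in the configuration:

* `regional_mean_series` (default): compute phenology on the region's
  area-weighted mean monthly SIC series, then classify that one season
  per year. This matches how regional seasonal cycles are usually
  presented and is the default.
* `pixel_fraction`: compute per-pixel seasons and trigger a category when
  the area fraction of marine pixels whose own season is critical reaches
  a cutoff (default 0.5). Kept as a sensitivity option; for homogeneous
  regions the two modes agree exactly, which the tests verify.

All regional statistics are area-weighted by per-pixel cell area: on a
projected Arctic grid, nominal 18 km cells differ in true area, and
regional means should not silently assume equal weights.

## The synthetic scenario

`generate_scenario()` emulates the statistical structure of a downscaled
high-emissions (RCP8.5-like) projection, not its physics:

* **Seasonal template: clipped sinusoid.** The raw annual cycle
  overshoots the winter maximum by 40% of the seasonal range and is
  clipped there, giving a flat winter plateau (roughly January–May for
  the default September minimum). This mirrors winter-saturated Arctic
  SIC, which sits at its maximum for months. It also has a structural
  consequence: each year's series is monotone from January down to the
  September minimum, so the first upward 10% crossing — freeze-up — can
  only occur on the autumn flank. Without the plateau (a plain sinusoid),
  a declining winter peak passes through a band where January sits below
  10% while March is still above it; the crossing rule then scores a
  one-month "season" and season lengths oscillate during the collapse.
  With the plateau, noise-free season lengths are nondecreasing
  throughout the decline, which is the behaviour a monotonically
  worsening scenario should show downstream.
* **Secular decline: uniform shift.** The configured decline rate
  (%/decade) shifts the whole cycle down each year before clipping to
  [0, 100]. A uniform shift makes the annual-mean trend equal the
  configured rate wherever clipping is inactive — which is what lets a
  regression on annual means recover the prescribed rate as a test — and
  reproduces the late-century loss of 100% winter maxima. Specifying
  `melt_out_year` instead derives the rate so the summer minimum first
  reaches zero in that year. A side effect of the winter plateau is that
  all plateau months cross the 50% break-up line in the same year, so
  regional season lengths grow in a few large steps rather than smoothly;
  the real system, with spatial heterogeneity within regions, would be
  more gradual.
* **Noise: one spatially correlated anomaly per year.** White noise
  box-smoothed over a configurable correlation length (default 2 pixels),
  rescaled to the target standard deviation (default 2% SIC), and added
  to all twelve months of the year. Interannual rather than monthly noise
  keeps each year's within-year shape valid while making year-to-year
  classification realistic. No variance or autocorrelation estimates
  exist for the original fields; these are free knobs, not calibrated
  values.
* **Thickness and snow links.** Thickness is
  `thickness_scale × (annual-mean noise-free SIC / 100)^2` (default scale
  3 m) and snow analogous (default 0.45 m, a realistic April peak on
  Arctic ice), each with small Gaussian noise, clipped at zero. The
  quadratic link preserves the co-decline of all three variables without
  modelling dynamics; late-century thickness ends up a factor of 2–5
  below the late-20th-century value, the right order for a strong-warming
  scenario.
* **Default demo.** 20 × 20 grid with a one-pixel land frame, seven
  latitudinal region bands named after the CAA populations, 1992–2100 on
  a no-leap calendar, winter maximum 100%, summer minimum 60%, and
  melt-out years 2025 (south) through 2060 (north), encoding the
  archipelago's south-to-north persistence gradient. Every region then
  traverses multiyear-dominated → annual-dominated → partially ice-free
  within the simulated century.

What the generator does *not* emulate: ice advection and export through
channels, within-region heterogeneity beyond smooth noise, skewed or
autocorrelated interannual variability, and any coupling between
thickness and the SIC cycle shape. Passing tests on synthetic data
therefore validate the *rules and their implementation*, not the realism
of any particular projection.

## Bias correction

`compute_monthly_bias()` implements the monthly-scale splice adjustment
used when switching a regional model's forcing from reanalysis to a
climate model: for each calendar month, the bias layer is the difference
(reference − model) or ratio (reference / model) of monthly means pooled
over a window of years (default 2005–2011, seven years — short for a
climatology, chosen to smooth a transition in a fast-trending climate).
`apply_bias()` applies the layer as a step function to every sub-monthly
step of that calendar month. Closure — corrected monthly means equal to
the reference's over the window, exact for differences and to float
precision for ratios — is the defining property and is tested
numerically. Ratio denominators are floored at `eps` (default 1e-6) and
ratios capped (default 10) because near-zero monthly means are otherwise
unstable; which physical variables use difference versus ratio is left to
the caller, as the source text does not decode its own variable groups.

## Numerical and degenerate-input choices

* Missing months: any missing month in a pixel-year makes that year's
  classification missing, since every rule quantifies over all twelve
  months; a missing month inside a freeze-up search window flags the
  season missing rather than guessing.
* Last year of a record has no look-ahead: if ice drops below 10% after
  break-up and never recovers before the record ends, freeze-up is capped
  at the earlier of twelve months past break-up and the record's end.
* SIC is canonically percent [0, 100]; fraction-valued inputs are
  converted exactly once at the read boundary, driven by the declared
  unit or, failing that, by a maximum at or below 1.5.
* Regions with no classified area in a year propagate `NA` rather than
  zero, to avoid silent bias in multi-year summaries.
* Gridded data are serialized as a JSON header (grid, time axis,
  calendar, units, land mask) plus a delimited long table; integers
  round-trip exactly and floats to a declared precision.

## Known limitations

* Only the first ice-free period per year is scored. For series with
  several dips below 10% per year, uniformly lowering SIC can
  legitimately *shorten* the scored season (a deeper first dip can create
  an earlier recovery crossing). The monotonicity guarantee — lower ice,
  never-shorter seasons — applies to winter-saturated single-dip cycles,
  which is what both the generator and real CAA seasonal cycles produce.
* Multiyear ice is a concentration proxy (15% year-round), not an
  ice-age calculation; true ice age is not recoverable from SIC alone.
* The point of no return depends on the record's end year by definition.
* Problem sizes in the tests and reproduction script (20 × 20 demo grid,
  109 years; 5 × 5 grids for parameter recovery; 10^4 randomized series
  for oracle equivalence) were chosen as the smallest sizes at which
  every qualitative feature of the analysis is expressed.

## A minimal worked example

```{r example, eval = FALSE}
sc <- generate_scenario(scenario_config(seed = 2024))
classes <- classify_fieldset(sc$fields)
proportions <- ice_type_proportions(classes, sc$mask)
phen <- phenology_fieldset(sc$fields)
head(breakup_area_fraction(phen, sc$mask, month = 7))
flags <- region_year_critical(sc$fields, sc$mask, region_id = 1)
point_of_no_return(flags[, "B"], sc$fields$years)
```

The `analysis/` directory runs this chain as six numbered stage scripts,
writing tables under `results/`.
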