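#' Expected baseline deaths by age band
#'
#' Converts the live-births series and baseline mortality rates into expected
#' deaths in the two age bands for a given year, using the cohort-synthetic
#' approximation `deaths = births * rate / 1000`; the 1-59-month band carries
#' the difference `u5mr0 - nmr0`. Births for years outside the series span
#' clamp to the nearest available year. Full life-table machinery (competing
#' ages, cohort carry-over) is deliberately out of scope: only the two rates
#' and exogenous births enter the model.
#'
#' @param demography A [demography()] object.
#' @param year Calendar year (numeric, may be a vector of length 1).
#' @return Named numeric vector: expected deaths in `"neonatal"` and
#'   `"1-59 months"`.
#' @examples
#' d <- demography(c("2008" = 1e5), nmr0 = 20, u5mr0 = 50)
#' band_deaths(d, 2008)  # neonatal 2000, 1-59 months 3000
#' @export
band_deaths <- function(demography, year) {
  stopifnot(inherits(demography, "demography"), length(year) == 1L)
  births <- interp_anchors(demography$live_births, year)
  stats::setNames(
    c(births * demography$nmr0 / 1000,
      births * (demography$u5mr0 - demography$nmr0) / 1000),
    AGE_BANDS)
}

#' Expected baseline deaths by age band and cause
#'
#' Splits [band_deaths()] across causes using the profile's cause-of-death
#' fractions. Deaths are real-valued throughout the engine; rounding to whole
#' children happens only in reporting.
#'
#' @param profile A `country_profile`.
#' @param year Calendar year.
#' @return A list keyed by age band; each element a named numeric vector of
#'   expected deaths by cause. The per-band sums equal [band_deaths()].
#' @export
baseline_cause_deaths <- function(profile, year) {
  stopifnot(inherits(profile, "country_profile"))
  totals <- band_deaths(profile$demography, year)
  out <- lapply(AGE_BANDS, function(b) profile$cod[[b]] * totals[[b]])
  stats::setNames(out, AGE_BANDS)
}
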