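#' Demographic inputs for a country profile
#'
#' Bundles an annual live-births series with the baseline neonatal and
#' under-five mortality rates. The two rates, expressed as deaths per 1,000
#' live births, define the expected deaths in the two modelled age bands
#' (neonatal, 1-59 months); the post-neonatal band carries `u5mr0 - nmr0`
#' deaths per 1,000 births.
#'
#' @param live_births Named numeric vector of live births; names are calendar
#'   years. All values must be positive.
#' @param nmr0 Baseline neonatal mortality rate, deaths per 1,000 live births.
#' @param u5mr0 Baseline under-five mortality rate, deaths per 1,000 live
#'   births. Must exceed `nmr0`.
#' @return An object of class `demography`.
#' @examples
#' demography(c("2008" = 850000, "2014" = 900000), nmr0 = 31.2, u5mr0 = 75.3)
#' @export
demography <- function(live_births, nmr0, u5mr0) {
  if (is.null(names(live_births)) || anyNA(suppressWarnings(as.numeric(names(live_births))))) {
    stop_validation("demography: live_births must be a numeric vector named by calendar year")
  }
  bad <- which(!is.finite(live_births) | live_births <= 0)
  if (length(bad)) {
    stop_validation("demography: live_births must be > 0 for every year; offending year ",
                    names(live_births)[bad[1]])
  }
  if (!is.finite(nmr0) || !is.finite(u5mr0) || nmr0 <= 0 || u5mr0 <= nmr0) {
    stop_validation("demography: rates must satisfy 0 < nmr0 < u5mr0 (got nmr0=",
                    nmr0, ", u5mr0=", u5mr0, ")")
  }
  yrs <- as.integer(names(live_births))
  o <- order(yrs)
  structure(
    list(years = yrs[o],
         live_births = stats::setNames(as.numeric(live_births)[o], yrs[o]),
         nmr0 = as.numeric(nmr0),
         u5mr0 = as.numeric(u5mr0)),
    class = "demography")
}

#' Cause-of-death fractions for both age bands
#'
#' @param neonatal Named numeric vector: fraction of neonatal deaths by cause.
#' @param post_neonatal Named numeric vector: fraction of 1-59-month deaths by
#'   cause. Each band's fractions must lie in \[0,1\] and sum to 1.
#' @return An object of class `cause_profile`: a list keyed by age band.
#' @export
cause_profile <- function(neonatal, post_neonatal) {
  check_band <- function(fr, band) {
    if (is.null(names(fr)) || any(!nzchar(names(fr)))) {
      stop_validation("cause_profile: ", band, " fractions must be named by cause")
    }
    if (any(fr < 0 | fr > 1)) {
      bad <- names(fr)[which(fr < 0 | fr > 1)[1]]
      stop_validation("cause_profile: fraction out of [0,1] for cause '", bad,
                      "' in band '", band, "'")
    }
    if (abs(sum(fr) - 1) > 1e-9) {
      stop_validation("cause_profile: fractions in band '", band,
                      "' sum to ", format(sum(fr), digits = 12), ", not 1")
    }
    stats::setNames(as.numeric(fr), names(fr))
  }
  structure(
    stats::setNames(
      list(check_band(neonatal, AGE_BANDS[1]), check_band(post_neonatal, AGE_BANDS[2])),
      AGE_BANDS),
    class = "cause_profile")
}

#' Herd-effect specification for an intervention
#'
#' Optional indirect protection at high coverage (vaccines, bed nets). Above
#' `threshold` coverage the effective coverage is boosted linearly, reaching a
#' multiplicative factor of `1 + max_boost` at 100% coverage, capped at 1.
#'
#' @param threshold Coverage proportion in \[0,1\] at which the boost begins.
#' @param max_boost Maximum multiplicative boost (>= 0) at full coverage.
#' @return An object of class `herd_spec`.
#' @seealso [effective_coverage()]
#' @export
herd_spec <- function(threshold, max_boost) {
  if (!is.finite(threshold) || threshold < 0 || threshold >= 1) {
    stop_validation("herd_spec: threshold must lie in [0,1)")
  }
  if (!is.finite(max_boost) || max_boost < 0) {
    stop_validation("herd_spec: max_boost must be >= 0")
  }
  structure(list(threshold = threshold, max_boost = max_boost), class = "herd_spec")
}

#' Define an intervention
#'
#' An intervention is characterised by its effectiveness E (proportion of
#' deaths from an amenable cause prevented in a covered child) and its
#' affected fractions AF (per cause, the fraction of cause-specific mortality
#' amenable to it). A child covered at proportion c avoids a fraction
#' `c * E * AF` of that cause's deaths.
#'
#' @param id Short unique identifier.
#' @param name Display name; defaults to `id`.
#' @param period Delivery period, one of `"pregnancy"`, `"childbirth"`,
#'   `"breastfeeding"`, `"preventive"`, `"vaccine"`, `"curative"`.
#' @param age_bands Character subset of `c("neonatal", "1-59 months")`.
#' @param effectiveness Proportion in \[0,1\].
#' @param affected_fractions Named numeric vector (cause -> proportion in
#'   \[0,1\]); at least one entry must be nonzero.
#' @param herd Optional [herd_spec()].
#' @return An object of class `intervention`.
#' @export
intervention <- function(id, name = id,
                         period = c("pregnancy", "childbirth", "breastfeeding",
                                    "preventive", "vaccine", "curative"),
                         age_bands = AGE_BANDS,
                         effectiveness,
                         affected_fractions,
                         herd = NULL) {
  period <- match.arg(period)
  if (!is.character(id) || length(id) != 1L || !nzchar(id)) {
    stop_validation("intervention: id must be a nonempty string")
  }
  if (!all(age_bands %in% AGE_BANDS)) {
    stop_validation("intervention '", id, "': age_bands must be a subset of {",
                    paste(AGE_BANDS, collapse = ", "), "}")
  }
  if (!is.finite(effectiveness) || effectiveness < 0 || effectiveness > 1) {
    stop_validation("intervention '", id, "': effectiveness must lie in [0,1]")
  }
  af <- affected_fractions
  if (is.null(names(af)) || any(!nzchar(names(af)))) {
    stop_validation("intervention '", id, "': affected_fractions must be named by cause")
  }
  if (any(af < 0 | af > 1)) {
    stop_validation("intervention '", id, "': affected fraction out of [0,1] for cause '",
                    names(af)[which(af < 0 | af > 1)[1]], "'")
  }
  if (all(af == 0)) {
    stop_validation("intervention '", id, "': at least one affected fraction must be nonzero")
  }
  if (!is.null(herd) && !inherits(herd, "herd_spec")) {
    stop_validation("intervention '", id, "': herd must be NULL or a herd_spec")
  }
  structure(
    list(id = id, name = name, period = period, age_bands = age_bands,
         effectiveness = as.numeric(effectiveness),
         affected_fractions = stats::setNames(as.numeric(af), names(af)),
         herd = herd),
    class = "intervention")
}

#' Coverage anchors for one intervention
#'
#' Coverage is stored in percent, exactly as printed in survey tables, and is
#' converted to a proportion once, at the engine boundary
#' ([interpolate_coverage()]). Queries between anchors interpolate linearly;
#' queries outside the anchored span clamp to the nearest anchor.
#'
#' @param intervention_id Identifier of the intervention the series covers.
#' @param anchors Named numeric vector (year -> percent in \[0,100\]).
#' @return An object of class `coverage_series`.
#' @export
coverage_series <- function(intervention_id, anchors) {
  if (length(anchors) < 1L) {
    stop_validation("coverage_series '", intervention_id, "': at least one anchor required")
  }
  if (is.null(names(anchors)) || anyNA(suppressWarnings(as.numeric(names(anchors))))) {
    stop_validation("coverage_series '", intervention_id, "': anchors must be named by year")
  }
  bad <- which(!is.finite(anchors) | anchors < 0 | anchors > 100)
  if (length(bad)) {
    stop_validation("coverage_series '", intervention_id, "': anchor at year ",
                    names(anchors)[bad[1]], " is ", anchors[bad[1]],
                    ", outside [0,100]")
  }
  yrs <- as.integer(names(anchors))
  o <- order(yrs)
  structure(
    list(intervention_id = intervention_id,
         anchors = stats::setNames(as.numeric(anchors)[o], yrs[o])),
    class = "coverage_series")
}

#' Define a nutrition risk factor (stunting or wasting)
#'
#' Risk-factor prevalence scales mortality from the causes it affects via the
#' population mean relative risk `P * RR + (1 - P)` (see [risk_scaler()]).
#' Prevalence can be driven either directly by its anchors (direct-entry mode)
#' or through linked nutrition interventions (intervention-only mode); the
#' profile `mode` selects exactly one channel to avoid double counting.
#'
#' @param name `"stunting"` or `"wasting"`.
#' @param prevalence_anchors Named numeric vector (year -> percent in
#'   \[0,100\]).
#' @param relative_risks Named numeric vector (cause -> RR >= 1).
#' @param linked_interventions Optional named numeric vector
#'   (intervention id -> prevalence-reduction efficacy in \[0,1\]).
#' @return An object of class `risk_factor`.
#' @export
risk_factor <- function(name = c("stunting", "wasting"),
                        prevalence_anchors,
                        relative_risks,
                        linked_interventions = NULL) {
  name <- match.arg(name)
  bad <- which(!is.finite(prevalence_anchors) | prevalence_anchors < 0 |
                 prevalence_anchors > 100)
  if (length(bad)) {
    stop_validation("risk_factor '", name, "': prevalence at year ",
                    names(prevalence_anchors)[bad[1]], " outside [0,100]")
  }
  if (any(relative_risks < 1)) {
    stop_validation("risk_factor '", name, "': relative risk < 1 for cause '",
                    names(relative_risks)[which(relative_risks < 1)[1]], "'")
  }
  if (!is.null(linked_interventions)) {
    if (is.null(names(linked_interventions)) ||
        any(linked_interventions < 0 | linked_interventions > 1)) {
      stop_validation("risk_factor '", name,
                      "': linked_interventions must map intervention id -> efficacy in [0,1]")
    }
  }
  yrs <- as.integer(names(prevalence_anchors))
  o <- order(yrs)
  structure(
    list(name = name,
         prevalence_anchors = stats::setNames(as.numeric(prevalence_anchors)[o], yrs[o]),
         relative_risks = stats::setNames(as.numeric(relative_risks), names(relative_risks)),
         linked_interventions = linked_interventions),
    class = "risk_factor")
}

#' Assemble and validate a country profile
#'
#' The full model input: demography, cause-of-death structure, intervention
#' definitions, coverage series, and optional risk factors. `mode` selects how
#' stunting/wasting enter the model: `"direct_entry"` drives the risk channels
#' from their prevalence anchors (and disables linked-intervention prevalence
#' effects), `"intervention_only"` derives prevalence trajectories from linked
#' nutrition interventions (anchors beyond baseline are ignored). The two
#' modes are mutually exclusive so the same prevalence decline is never
#' counted twice.
#'
#' @param name Profile label.
#' @param demography A [demography()] object.
#' @param cod A [cause_profile()] object.
#' @param interventions List of [intervention()] objects with unique ids.
#' @param coverages List of [coverage_series()], exactly one per intervention.
#' @param risk_factors Optional list of [risk_factor()] objects.
#' @param mode `"direct_entry"` or `"intervention_only"`.
#' @return A validated object of class `country_profile`.
#' @export
country_profile <- function(name, demography, cod, interventions, coverages,
                            risk_factors = list(),
                            mode = c("direct_entry", "intervention_only")) {
  mode <- match.arg(mode)
  p <- structure(
    list(name = name, demography = demography, cod = cod,
         interventions = interventions, coverages = coverages,
         risk_factors = risk_factors, mode = mode),
    class = "country_profile")
  validate_profile(p)
}

#' Validate a country profile
#'
#' Checks every structural invariant: component classes, unique intervention
#' ids, one-to-one correspondence between coverage series and interventions,
#' causes referenced by affected fractions and relative risks present in the
#' cause-of-death profile of a shared age band, and risk-factor links that
#' resolve to existing interventions.
#'
#' @param profile A `country_profile`.
#' @return The profile, invisibly usable, unchanged; errors on violation.
#' @export
validate_profile <- function(profile) {
  if (!inherits(profile, "country_profile")) {
    stop_validation("validate_profile: not a country_profile")
  }
  if (!inherits(profile$demography, "demography")) {
    stop_validation("profile '", profile$name, "': demography field is not a demography object")
  }
  if (!inherits(profile$cod, "cause_profile")) {
    stop_validation("profile '", profile$name, "': cod field is not a cause_profile")
  }
  ids <- vapply(profile$interventions, function(x) x$id, character(1))
  if (anyDuplicated(ids)) {
    stop_validation("profile '", profile$name, "': duplicate intervention id '",
                    ids[duplicated(ids)][1], "'")
  }
  cov_ids <- vapply(profile$coverages, function(x) x$intervention_id, character(1))
  orphan <- setdiff(cov_ids, ids)
  if (length(orphan)) {
    stop_validation("profile '", profile$name, "': unknown intervention id '",
                    orphan[1], "' in coverage series")
  }
  missing_cov <- setdiff(ids, cov_ids)
  if (length(missing_cov)) {
    stop_validation("profile '", profile$name, "': intervention '", missing_cov[1],
                    "' has no coverage series")
  }
  if (anyDuplicated(cov_ids)) {
    stop_validation("profile '", profile$name, "': duplicate coverage series for '",
                    cov_ids[duplicated(cov_ids)][1], "'")
  }
  for (iv in profile$interventions) {
    causes_in_bands <- unique(unlist(lapply(iv$age_bands, function(b) names(profile$cod[[b]]))))
    unknown <- setdiff(names(iv$affected_fractions), causes_in_bands)
    if (length(unknown)) {
      stop_validation("profile '", profile$name, "': intervention '", iv$id,
                      "' affects cause '", unknown[1],
                      "' absent from its age bands' cause profile")
    }
  }
  for (rf in profile$risk_factors) {
    if (!inherits(rf, "risk_factor")) {
      stop_validation("profile '", profile$name, "': risk_factors must contain risk_factor objects")
    }
    if (!is.null(rf$linked_interventions)) {
      unknown <- setdiff(names(rf$linked_interventions), ids)
      if (length(unknown)) {
        stop_validation("profile '", profile$name, "': risk factor '", rf$name,
                        "' links unknown intervention id '", unknown[1], "'")
      }
    }
    if (profile$mode == "intervention_only" &&
        is.null(rf$linked_interventions) && length(rf$relative_risks)) {
      # Allowed: the factor is simply inert in this mode (no driver).
    }
  }
  profile
}

#' @export
print.country_profile <- function(x, ...) {
  yrs <- range(x$demography$years)
  cat("Country profile:", x$name, "\n")
  cat("  span          :", yrs[1], "-", yrs[2], "\n")
  cat("  baseline rates: NMR", x$demography$nmr0, "| U5MR", x$demography$u5mr0,
      "per 1,000 live births\n")
  cat("  causes        :", length(x$cod[[1]]), "neonatal /", length(x$cod[[2]]),
      "post-neonatal\n")
  cat("  interventions :", length(x$interventions), "\n")
  cat("  risk factors  :", if (length(x$risk_factors))
    paste(vapply(x$risk_factors, `[[`, "", "name"), collapse = ", ") else "none", "\n")
  cat("  mode          :", x$mode, "\n")
  invisible(x)
}
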