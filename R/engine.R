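# Impact engine: coverage interpolation, residual mortality under an
# intervention portfolio, risk-factor scaling, and per-channel attribution.
#
# The model is multiplicative within a cause: each intervention i active on a
# (cause, band) contributes a residual term 1 - c_i * E_i * AF_i, and the
# surviving fraction of that cause's deaths is the product of the terms.
# Risk factors (stunting, wasting) multiply cause deaths by the ratio of
# population mean relative risks at current vs baseline prevalence.

#' Interpolated coverage as a proportion
#'
#' Linear interpolation between the series' percent anchors, converted to a
#' proportion; queries outside the anchored span clamp to the nearest anchor.
#' This is the single point where percent (storage/tables) becomes proportion
#' (engine).
#'
#' @param series A [coverage_series()].
#' @param year Calendar year(s).
#' @return Coverage proportion(s) in \[0,1\].
#' @examples
#' s <- coverage_series("itn", c("2008" = 41.7, "2014" = 70.9))
#' interpolate_coverage(s, 2014)  # 0.709
#' interpolate_coverage(s, 2011)  # 0.563
#' @export
interpolate_coverage <- function(series, year) {
  stopifnot(inherits(series, "coverage_series"))
  interp_anchors(series$anchors, year) / 100
}

#' Effective coverage under an optional herd effect
#'
#' Without a herd specification this is the identity. With one, coverage above
#' the threshold is boosted linearly up to a factor `1 + max_boost` at 100%
#' coverage, capped at 1:
#' `c_eff = min(1, c * (1 + max_boost * max(0, c - threshold) / (1 - threshold)))`.
#' The map is continuous and nondecreasing in `c`, and equals `c` at or below
#' the threshold.
#'
#' @param c Coverage proportion(s) in \[0,1\].
#' @param herd A [herd_spec()] or `NULL` (default: no herd effect).
#' @return Effective coverage proportion(s) in \[0,1\].
#' @export
effective_coverage <- function(c, herd = NULL) {
  stopifnot(all(c >= 0 & c <= 1))
  if (is.null(herd)) return(c)
  boost <- herd$max_boost * pmax(0, c - herd$threshold) / (1 - herd$threshold)
  pmin(1, c * (1 + boost))
}

#' Residual factor of a cause under an intervention portfolio
#'
#' The fraction of a cause's deaths in an age band NOT averted by the
#' portfolio: the product over interventions active on that (cause, band) of
#' `1 - c_eff * E * AF`. An empty portfolio gives 1. Herd effects declared on
#' individual interventions are applied to their coverages.
#'
#' @param interventions List of [intervention()] objects.
#' @param coverages Named numeric vector, intervention id -> coverage
#'   proportion in \[0,1\].
#' @param cause Cause name.
#' @param age_band `"neonatal"` or `"1-59 months"`.
#' @return A proportion in \[0,1\].
#' @examples
#' iv <- intervention("a", period = "curative", effectiveness = 0.6,
#'                    affected_fractions = c(malaria = 0.5))
#' residual_factor(list(iv, iv), c(a = 0.5), "malaria", "1-59 months")
#' @export
residual_factor <- function(interventions, coverages, cause, age_band) {
  stopifnot(all(coverages >= 0 & coverages <= 1))
  value <- 1
  for (iv in interventions) {
    af <- iv$affected_fractions[cause]
    if (is.na(af) || af == 0 || !(age_band %in% iv$age_bands)) next
    cc <- coverages[[iv$id]]
    if (is.null(cc)) {
      stop_validation("residual_factor: no coverage supplied for intervention '",
                      iv$id, "'")
    }
    ceff <- effective_coverage(cc, iv$herd)
    value <- value * (1 - ceff * iv$effectiveness * as.numeric(af))
  }
  value
}

#' Population mean relative risk at a given prevalence
#'
#' With a fraction `P` of children exposed to a risk factor carrying relative
#' risk `RR` for a cause, the population's mean relative risk is
#' `P * RR + (1 - P)`. It is >= 1 and increasing in both arguments; cause
#' deaths under changing prevalence scale by the ratio of this quantity at
#' current vs baseline prevalence.
#'
#' @param P Prevalence proportion(s) in \[0,1\].
#' @param RR Relative risk(s) >= 1.
#' @return Mean relative risk(s), >= 1.
#' @examples
#' risk_scaler(0.5, 3)    # 2
#' risk_scaler(0.086, 2)  # 1.086
#' @export
risk_scaler <- function(P, RR) {
  stopifnot(all(P >= 0 & P <= 1), all(RR >= 1))
  P * RR + (1 - P)
}

# --- internal: per-year channel state -------------------------------------

# Coverage proportions for every series at `year` (named by intervention id).
coverage_map <- function(profile, year) {
  stats::setNames(
    vapply(profile$coverages, function(s) interpolate_coverage(s, year),
           numeric(1), USE.NAMES = FALSE),
    vapply(profile$coverages, `[[`, "", "intervention_id"))
}

# Prevalence proportions for every risk factor at `year`, honouring the mode.
# In direct_entry mode prevalence follows its anchors. In intervention_only
# mode it equals the baseline-anchor value scaled by the linked interventions'
# relative prevalence reduction from their t0 coverages:
#   P(t) = P(t0) * prod_l (1 - c_l(t) e_l) / (1 - c_l(t0) e_l)
prevalence_map <- function(profile, year, t0, covs = NULL, covs0 = NULL) {
  if (!length(profile$risk_factors)) return(stats::setNames(numeric(0), character(0)))
  if (is.null(covs)) covs <- coverage_map(profile, year)
  if (is.null(covs0)) covs0 <- coverage_map(profile, t0)
  out <- vapply(profile$risk_factors, function(rf) {
    if (profile$mode == "direct_entry" || is.null(rf$linked_interventions)) {
      if (profile$mode == "direct_entry") {
        interp_anchors(rf$prevalence_anchors, year) / 100
      } else {
        # intervention_only with no links: inert, held at baseline.
        interp_anchors(rf$prevalence_anchors, t0) / 100
      }
    } else {
      p0 <- interp_anchors(rf$prevalence_anchors, t0) / 100
      ratio <- 1
      for (l in names(rf$linked_interventions)) {
        e <- rf$linked_interventions[[l]]
        ratio <- ratio * (1 - covs[[l]] * e) / (1 - covs0[[l]] * e)
      }
      min(1, p0 * ratio)
    }
  }, numeric(1))
  stats::setNames(out, vapply(profile$risk_factors, `[[`, "", "name"))
}

#' Cause-specific deaths under scenario coverages and prevalences
#'
#' Projects expected deaths per (age band, cause) for `year` given a map of
#' coverage proportions and risk-factor prevalence proportions, relative to
#' the profile's baseline-year portfolio:
#' `deaths = baseline * residual(t)/residual(t0) * prod_r rho_r(t)/rho_r(t0)`.
#' The normalisation by the baseline-year factors guarantees that supplying
#' the baseline coverages and prevalences reproduces the baseline deaths
#' exactly — no change in coverage means zero lives saved.
#'
#' @param profile A `country_profile`.
#' @param coverages_at_t Named numeric vector, id -> coverage proportion.
#' @param prevalences_at_t Named numeric vector, risk-factor name ->
#'   prevalence proportion (may be empty if the profile has no risk factors).
#' @param year Calendar year (sets the births cohort).
#' @return List keyed by age band of named numeric vectors of deaths by cause.
#' @export
cause_deaths_under_scenario <- function(profile, coverages_at_t,
                                        prevalences_at_t = NULL, year) {
  stopifnot(inherits(profile, "country_profile"))
  t0 <- min(profile$demography$years)
  covs0 <- coverage_map(profile, t0)
  prevs0 <- prevalence_map(profile, t0, t0)
  if (is.null(prevalences_at_t)) prevalences_at_t <- prevs0
  base <- baseline_cause_deaths(profile, year)
  out <- lapply(AGE_BANDS, function(band) {
    causes <- names(base[[band]])
    vals <- vapply(causes, function(cs) {
      r0 <- residual_factor(profile$interventions, covs0, cs, band)
      if (r0 == 0) {
        stop_degenerate("cause '", cs, "' in band '", band,
                        "' is fully averted at baseline (residual factor 0)")
      }
      rt <- residual_factor(profile$interventions, coverages_at_t, cs, band)
      rr_ratio <- 1
      for (rf in profile$risk_factors) {
        RR <- rf$relative_risks[cs]
        if (is.na(RR)) next
        rr_ratio <- rr_ratio *
          risk_scaler(prevalences_at_t[[rf$name]], RR) / risk_scaler(prevs0[[rf$name]], RR)
      }
      base[[band]][[cs]] * (rt / r0) * rr_ratio
    }, numeric(1))
    stats::setNames(vals, causes)
  })
  stats::setNames(out, AGE_BANDS)
}

#' Attribute jointly averted deaths to individual channels
#'
#' Given one (band, cause, year) cell with baseline deaths `D0` and per-channel
#' multiplicative factors at baseline (`factors_t0`) and at the scenario time
#' (`factors_t1`), the joint deaths averted are
#' `D0 * (1 - prod(factors_t1)/prod(factors_t0))`. Each channel receives the
#' share `w_i / sum(w)` of that total, with the signed log weight
#' `w_i = log(f_i(t0)) - log(f_i(t1))`. The scheme is order-independent, sums
#' exactly to the joint total, gives exactly zero to unchanged channels, and
#' reduces to the closed form for a single channel. A channel whose coverage
#' fell carries a negative weight and receives a negative allocation. When the
#' weights cancel exactly (offsetting changes, zero net), the continuous limit
#' `D0 * w_i` is used.
#'
#' @param baseline_deaths Baseline deaths `D0` in the cell (scalar).
#' @param factors_t0,factors_t1 Named numeric vectors of per-channel residual
#'   terms in (0, 1\] (interventions) or mean-relative-risk factors (risk
#'   channels), at baseline and scenario time; same names.
#' @return Named numeric vector of deaths averted per channel.
#' @export
attribute_lives_saved <- function(baseline_deaths, factors_t0, factors_t1) {
  stopifnot(length(factors_t0) == length(factors_t1),
            identical(names(factors_t0), names(factors_t1)))
  if (any(factors_t0 <= 0) || any(factors_t1 <= 0)) {
    stop_degenerate("attribute_lives_saved: channel factors must be positive")
  }
  if (!length(factors_t0)) return(stats::setNames(numeric(0), character(0)))
  w <- log(factors_t0) - log(factors_t1)
  total <- baseline_deaths * (1 - prod(factors_t1) / prod(factors_t0))
  sw <- sum(w)
  if (abs(sw) < 1e-12) {
    if (abs(total) > 1e-9 * max(baseline_deaths, 1)) {
      stop("attribute_lives_saved: zero net log-weight with nonzero total; ",
           "inconsistent channel factors")
    }
    return(stats::setNames(baseline_deaths * w, names(w)))
  }
  stats::setNames(total * w / sw, names(w))
}

#' Lives saved by an intervention portfolio over a period
#'
#' Runs the deterministic model year by year over `(t0, t1]`. For each year
#' the coverages and risk-factor prevalences are interpolated, expected deaths
#' are computed both under the scenario and under the counterfactual in which
#' every channel is held at its `t0` value, and the difference is attributed
#' to channels by signed log-residual shares per (band, cause). Recomputing
#' the held-at-baseline counterfactual each year means children saved by a
#' coverage change are not re-saved in later years by the same change.
#'
#' In `direct_entry` mode the stunting/wasting channels follow their
#' prevalence anchors and appear in the ledger under their own names; in
#' `intervention_only` mode prevalence is driven by linked nutrition
#' interventions and the risk-channel impact is credited to those
#' interventions.
#'
#' @param profile A `country_profile`.
#' @param t0 Baseline year (counterfactual anchor).
#' @param t1 Endline year, `> t0`.
#' @param mode Analysis mode; defaults to the profile's.
#' @return An object of class `lives_saved_result` with components `ledger`
#'   (data frame: channel, year, age_band, averted), `totals` (named vector
#'   per channel), `grand_total`, `shares` (percent of grand total, unrounded),
#'   `deaths` (scenario vs counterfactual deaths per year and band), `rates`
#'   (scenario NMR/U5MR per year), `mode`, and `span`.
#' @examples
#' cf <- gen_closed_form_case(0, 0.6, 0.5, 1, 1000)
#' res <- lives_saved(cf$profile, 2008, 2009)
#' res$grand_total  # 300
#' @export
lives_saved <- function(profile, t0, t1, mode = profile$mode) {
  stopifnot(inherits(profile, "country_profile"))
  if (!(t0 < t1)) stop_validation("lives_saved: t0 must precede t1")
  profile$mode <- match.arg(mode, c("direct_entry", "intervention_only"))

  years <- seq.int(t0 + 1L, t1)
  covs0 <- coverage_map(profile, t0)
  prevs0 <- prevalence_map(profile, t0, t0)
  rf_names <- vapply(profile$risk_factors, `[[`, "", "name")
  iv_ids <- vapply(profile$interventions, `[[`, "", "id")

  # Channels carried in the ledger: interventions always; named risk channels
  # only in direct_entry mode (in intervention_only the risk pathway is
  # credited to the linked interventions).
  channels <- c(iv_ids, if (profile$mode == "direct_entry") rf_names)
  cells <- expand.grid(year = years, age_band = AGE_BANDS,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  acc <- matrix(0, nrow = length(channels), ncol = nrow(cells),
                dimnames = list(channels, NULL))
  scen_deaths <- cf_deaths <- numeric(nrow(cells))

  iv_by_id <- stats::setNames(profile$interventions, iv_ids)

  for (yi in seq_along(years)) {
    y <- years[yi]
    covs <- coverage_map(profile, y)
    prevs <- prevalence_map(profile, y, t0, covs, covs0)
    base <- baseline_cause_deaths(profile, y)
    for (band in AGE_BANDS) {
      col <- which(cells$year == y & cells$age_band == band)
      for (cs in names(base[[band]])) {
        D0 <- base[[band]][[cs]]
        f0 <- f1 <- numeric(0)
        for (iv in profile$interventions) {
          af <- iv$affected_fractions[cs]
          if (is.na(af) || af == 0 || !(band %in% iv$age_bands)) next
          ea <- iv$effectiveness * as.numeric(af)
          f0[iv$id] <- 1 - effective_coverage(covs0[[iv$id]], iv$herd) * ea
          f1[iv$id] <- 1 - effective_coverage(covs[[iv$id]], iv$herd) * ea
        }
        if (any(f0 == 0)) {
          stop_degenerate("cause '", cs, "' in band '", band,
                          "' is fully averted at baseline (residual factor 0)")
        }
        for (rf in profile$risk_factors) {
          RR <- rf$relative_risks[cs]
          if (is.na(RR)) next
          key <- paste0(".risk.", rf$name)
          f0[key] <- risk_scaler(prevs0[[rf$name]], RR)
          f1[key] <- risk_scaler(prevs[[rf$name]], RR)
        }
        scen <- D0 * if (length(f1)) prod(f1) / prod(f0) else 1
        scen_deaths[col] <- scen_deaths[col] + scen
        cf_deaths[col] <- cf_deaths[col] + D0
        if (!length(f0)) next
        alloc <- attribute_lives_saved(D0, f0, f1)
        for (ch in names(alloc)) {
          if (!startsWith(ch, ".risk.")) {
            acc[ch, col] <- acc[ch, col] + alloc[[ch]]
            next
          }
          rf <- profile$risk_factors[[match(sub("^\\.risk\\.", "", ch), rf_names)]]
          if (profile$mode == "direct_entry") {
            acc[rf$name, col] <- acc[rf$name, col] + alloc[[ch]]
          } else {
            # Split the risk channel across its linked interventions by their
            # log prevalence-reduction contributions (exact-summing).
            v <- vapply(names(rf$linked_interventions), function(l) {
              e <- rf$linked_interventions[[l]]
              log(1 - covs0[[l]] * e) - log(1 - covs[[l]] * e)
            }, numeric(1))
            if (sum(abs(v)) > 0) {
              for (l in names(v)) {
                acc[l, col] <- acc[l, col] + alloc[[ch]] * v[[l]] / sum(v)
              }
            }
          }
        }
      }
    }
  }

  ledger <- data.frame(
    channel = rep(channels, times = nrow(cells)),
    year = rep(cells$year, each = length(channels)),
    age_band = rep(cells$age_band, each = length(channels)),
    averted = as.vector(acc),
    stringsAsFactors = FALSE)
  totals <- rowSums(acc)
  grand_total <- sum(totals)
  shares <- if (abs(grand_total) > 0) 100 * totals / grand_total else
    stats::setNames(rep(NA_real_, length(totals)), names(totals))
  deaths <- data.frame(cells, scenario_deaths = scen_deaths,
                       counterfactual_deaths = cf_deaths,
                       stringsAsFactors = FALSE)

  res <- structure(
    list(mode = profile$mode, span = c(t0 = t0, t1 = t1), ledger = ledger,
         totals = totals, grand_total = grand_total, shares = shares,
         deaths = deaths, profile_name = profile$name),
    class = "lives_saved_result")
  res$rates <- counterfactual_rates(
    profile, deaths[, c("year", "age_band", "scenario_deaths")])
  res
}
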