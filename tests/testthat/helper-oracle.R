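# Independent brute-force oracle for the impact engine, plus small profile
# builders. The oracle re-derives everything from the profile fields with its
# own interpolation and plain nested loops: it shares no code path with
# lives_saved()/cause_deaths_under_scenario(), so agreement is evidence, not
# tautology. It assumes no herd effects and direct-entry risk factors (the
# configurations the property suites use).

oracle_interp <- function(anchors, year) {
  yrs <- as.numeric(names(anchors))
  v <- as.numeric(anchors)
  o <- order(yrs)
  yrs <- yrs[o]; v <- v[o]
  if (year <= yrs[1]) return(v[1])
  n <- length(yrs)
  if (year >= yrs[n]) return(v[n])
  i <- max(which(yrs <= year))
  v[i] + (v[i + 1] - v[i]) * (year - yrs[i]) / (yrs[i + 1] - yrs[i])
}

# Expected deaths in `year` with all channels evaluated at `at` (a year),
# relative to channels evaluated at `t0` (the counterfactual normalisation).
oracle_scenario_deaths <- function(profile, year, at, t0) {
  births <- oracle_interp(profile$demography$live_births, year)
  bands <- c("neonatal", "1-59 months")
  total <- 0
  for (band in bands) {
    rate <- if (band == "neonatal") profile$demography$nmr0 else
      profile$demography$u5mr0 - profile$demography$nmr0
    for (cs in names(profile$cod[[band]])) {
      D0 <- births * rate / 1000 * profile$cod[[band]][[cs]]
      ratio <- 1
      for (iv in profile$interventions) {
        af <- iv$affected_fractions[cs]
        if (is.na(af) || af == 0 || !(band %in% iv$age_bands)) next
        sr <- profile$coverages[[
          which(vapply(profile$coverages, `[[`, "", "intervention_id") == iv$id)]]
        term <- function(yy) 1 - oracle_interp(sr$anchors, yy) / 100 *
          iv$effectiveness * as.numeric(af)
        ratio <- ratio * term(at) / term(t0)
      }
      for (rf in profile$risk_factors) {
        RR <- rf$relative_risks[cs]
        if (is.na(RR)) next
        rho <- function(yy) {
          P <- oracle_interp(rf$prevalence_anchors, yy) / 100
          P * RR + (1 - P)
        }
        ratio <- ratio * rho(at) / rho(t0)
      }
      total <- total + D0 * ratio
    }
  }
  total
}

# Total deaths averted over (t0, t1]: scenario vs held-at-t0, year by year.
oracle_total_averted <- function(profile, t0, t1) {
  sum(vapply(seq.int(t0 + 1, t1), function(y) {
    oracle_scenario_deaths(profile, y, at = t0, t0 = t0) -
      oracle_scenario_deaths(profile, y, at = y, t0 = t0)
  }, numeric(1)))
}

# A minimal hand-built profile: one cause per band, interventions given as a
# list of list(id, E, AF, band, anchors_pct), optional direct-entry risk spec.
make_profile <- function(ivs, years = c(2008, 2014), births = 1e5,
                         nmr0 = 20, u5mr0 = 50, risk = NULL,
                         mode = "direct_entry") {
  dem <- demography(stats::setNames(rep(births, 2), years), nmr0, u5mr0)
  cod <- cause_profile(c(neo_cause = 1), c(post_cause = 1))
  iv_objs <- lapply(ivs, function(v) {
    intervention(v$id, period = "curative",
                 age_bands = if (v$band == "neonatal") "neonatal" else
                   c("neonatal", "1-59 months")[2],
                 effectiveness = v$E,
                 affected_fractions = stats::setNames(
                   v$AF, if (v$band == "neonatal") "neo_cause" else "post_cause"),
                 herd = v$herd %||% NULL)
  })
  covs <- lapply(ivs, function(v) {
    coverage_series(v$id, stats::setNames(v$anchors_pct, years[seq_along(v$anchors_pct)]))
  })
  rfs <- if (is.null(risk)) list() else list(
    risk_factor(risk$name, stats::setNames(risk$prev_pct, years),
                relative_risks = risk$rr))
  country_profile("test", dem, cod, iv_objs, covs, rfs, mode = mode)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
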