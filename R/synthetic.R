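# Seeded synthetic country profiles. The generator emulates the structure of
# a LiST-style national database — a two-anchor (baseline/endline) coverage
# table over ~dozens of interventions grouped by delivery period, a handful
# of causes per age band with sparse affected fractions, and stunting/wasting
# risk factors with declining prevalence — with known ground truth, so every
# stage of the engine is testable without any external data. Synthetic values
# are labelled synthetic; no attempt is made to mirror any real country's
# effectiveness database.

# Delivery-period templates: which age bands a period's interventions act on
# and the coverage range its baseline anchors are drawn from. Vaccines start
# high (mature programmes), curative/preventive lower, mirroring the spread
# seen in national coverage tables.
PERIODS <- list(
  pregnancy     = list(bands = "neonatal",             base = c(10, 90)),
  childbirth    = list(bands = "neonatal",             base = c(10, 80)),
  breastfeeding = list(bands = c("neonatal", "1-59 months"), base = c(30, 70)),
  preventive    = list(bands = "1-59 months",          base = c(0, 80)),
  vaccine       = list(bands = "1-59 months",          base = c(50, 95)),
  curative      = list(bands = c("neonatal", "1-59 months"), base = c(0, 70)))

NEONATAL_CAUSES <- c("prematurity", "birth asphyxia", "neonatal sepsis",
                     "neonatal tetanus", "congenital anomalies", "neonatal other")
POSTNEONATAL_CAUSES <- c("malaria", "pneumonia", "diarrhoea", "measles",
                         "meningitis", "injuries", "HIV", "other")

#' Configuration for the synthetic profile generator
#'
#' Defaults describe a mid-2010s high-mortality setting: baseline NMR 31.2
#' and U5MR 75.3 deaths per 1,000 live births, a birth cohort of 850,000
#' growing 2% a year, two coverage anchors six years apart (2008/2014), 20
#' interventions touching 1-2 causes each with effectiveness in \[0.2, 0.9\],
#' and stunting/wasting risk factors with relative risks in \[1.5, 4\] on the
#' infectious causes.
#'
#' @param seed Integer RNG seed; the generator is deterministic given it.
#' @param n_interventions,n_causes Portfolio and per-band cause-list sizes.
#' @param years Length-2 vector: baseline and endline anchor years.
#' @param births0 Live births in the baseline year.
#' @param births_growth Annual growth rate of the births series.
#' @param nmr0,u5mr0 Baseline mortality rates per 1,000 live births.
#' @param eff_range,af_range Ranges for effectiveness and affected fractions.
#' @param causes_per_intervention Candidate counts of causes an intervention
#'   touches (sampled uniformly).
#' @param delta_range Range of the endline-minus-baseline coverage change in
#'   percentage points (negative values allowed: programmes do regress).
#' @param include_risk_factors Add stunting and wasting?
#' @param rr_range Range for cause-specific relative risks.
#' @param mode Profile analysis mode.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(seed = 1L, n_interventions = 20L, n_causes = 6L,
                         years = c(2008L, 2014L),
                         births0 = 850000, births_growth = 0.02,
                         nmr0 = 31.2, u5mr0 = 75.3,
                         eff_range = c(0.2, 0.9), af_range = c(0.1, 0.8),
                         causes_per_intervention = c(1L, 2L),
                         delta_range = c(-15, 40),
                         include_risk_factors = TRUE,
                         rr_range = c(1.5, 4),
                         mode = c("direct_entry", "intervention_only")) {
  mode <- match.arg(mode)
  if (n_interventions < 1L) stop_validation("synth_config: n_interventions must be >= 1")
  if (n_causes < 1L) stop_validation("synth_config: n_causes must be >= 1")
  if (length(years) != 2L || years[2] <= years[1]) {
    stop_validation("synth_config: years must be two increasing anchor years")
  }
  if (eff_range[1] < 0 || eff_range[2] > 1 || af_range[1] < 0 || af_range[2] > 1) {
    stop_validation("synth_config: effectiveness/affected-fraction ranges must lie in [0,1]")
  }
  if (any(rr_range < 1)) stop_validation("synth_config: relative risks must be >= 1")
  if (!(nmr0 > 0 && u5mr0 > nmr0)) {
    stop_validation("synth_config: need 0 < nmr0 < u5mr0")
  }
  structure(as.list(environment()), class = "synth_config")
}

#' Generate a synthetic country profile
#'
#' Deterministic for a fixed seed (the seed is applied locally; global random
#' state is untouched). The produced profile passes every `country_profile`
#' invariant: per-band cause fractions sum to 1, coverages lie in \[0,100\],
#' each intervention has a coverage series, and risk-factor links resolve.
#'
#' @param config A [synth_config()].
#' @return A validated `country_profile`.
#' @examples
#' p <- gen_profile(synth_config(seed = 42))
#' length(p$interventions)  # 20
#' @export
gen_profile <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  with_local_seed(config$seed, {
    years <- seq.int(config$years[1], config$years[2])
    births <- config$births0 * (1 + config$births_growth)^(years - years[1])
    dem <- demography(stats::setNames(births, years), config$nmr0, config$u5mr0)

    n_neo <- min(config$n_causes, length(NEONATAL_CAUSES))
    n_post <- min(config$n_causes, length(POSTNEONATAL_CAUSES))
    neo_causes <- NEONATAL_CAUSES[seq_len(n_neo)]
    post_causes <- POSTNEONATAL_CAUSES[seq_len(n_post)]
    dirichlet <- function(k) { g <- stats::rgamma(k, shape = 2); g / sum(g) }
    cod <- cause_profile(stats::setNames(dirichlet(n_neo), neo_causes),
                         stats::setNames(dirichlet(n_post), post_causes))

    period_names <- names(PERIODS)
    ivs <- vector("list", config$n_interventions)
    covs <- vector("list", config$n_interventions)
    for (i in seq_len(config$n_interventions)) {
      period <- period_names[1 + (i - 1) %% length(period_names)]
      tmpl <- PERIODS[[period]]
      band_causes <- unique(unlist(
        lapply(tmpl$bands, function(b) if (b == "neonatal") neo_causes else post_causes)))
      k <- sample(config$causes_per_intervention, 1)
      touched <- sample(band_causes, min(k, length(band_causes)))
      af <- stats::setNames(stats::runif(length(touched), config$af_range[1],
                                         config$af_range[2]), touched)
      id <- sprintf("iv%02d", i)
      ivs[[i]] <- intervention(
        id = id, name = paste0("synthetic ", period, " intervention ", i),
        period = period, age_bands = tmpl$bands,
        effectiveness = stats::runif(1, config$eff_range[1], config$eff_range[2]),
        affected_fractions = af,
        herd = NULL)
      c0 <- stats::runif(1, tmpl$base[1], tmpl$base[2])
      c1 <- min(100, max(0, c0 + stats::runif(1, config$delta_range[1],
                                              config$delta_range[2])))
      covs[[i]] <- coverage_series(id, stats::setNames(c(c0, c1), config$years))
    }

    risk_factors <- list()
    if (config$include_risk_factors) {
      infectious <- intersect(c("malaria", "pneumonia", "diarrhoea"), post_causes)
      link_pool <- vapply(ivs, `[[`, "", "id")[
        vapply(ivs, function(iv) iv$period %in% c("preventive", "breastfeeding"),
               logical(1))]
      mk <- function(nm, p0_range, drop_range) {
        p0 <- stats::runif(1, p0_range[1], p0_range[2])
        p1 <- max(0.5, p0 - stats::runif(1, drop_range[1], drop_range[2]))
        risk_factor(
          name = nm,
          prevalence_anchors = stats::setNames(c(p0, p1), config$years),
          relative_risks = stats::setNames(
            stats::runif(length(infectious), config$rr_range[1], config$rr_range[2]),
            infectious),
          linked_interventions = if (length(link_pool))
            stats::setNames(stats::runif(1, 0.1, 0.4), sample(link_pool, 1)))
      }
      risk_factors <- list(mk("stunting", c(20, 35), c(3, 10)),
                           mk("wasting", c(5, 12), c(1, 5)))
    }

    country_profile(
      name = sprintf("synthetic-%d", config$seed),
      demography = dem, cod = cod, interventions = ivs, coverages = covs,
      risk_factors = risk_factors, mode = config$mode)
  })
}

#' Single-intervention profile with closed-form ground truth
#'
#' Builds a one-cause, one-intervention, two-year profile whose exact
#' lives-saved value over the single annual step is
#' `deaths * (c1 - c0) * E * AF / (1 - c0 * E * AF)`:
#' the deaths averted when coverage moves from `c0` to `c1` against the
#' held-at-`c0` counterfactual. Used as an analytic oracle for the engine.
#'
#' @param c0,c1 Baseline and endline coverage proportions in \[0,1\].
#' @param E Effectiveness in \[0,1\].
#' @param AF Affected fraction in (0,1\].
#' @param deaths Baseline annual deaths from the single cause.
#' @return List with elements `profile` (a `country_profile` spanning two
#'   years) and `expected` (the closed-form lives saved).
#' @examples
#' gen_closed_form_case(0, 0.6, 0.5, 1, 1000)$expected  # 300
#' @export
gen_closed_form_case <- function(c0, c1, E, AF, deaths) {
  stopifnot(c0 >= 0, c0 <= 1, c1 >= 0, c1 <= 1, E >= 0, E <= 1,
            AF > 0, AF <= 1, deaths > 0)
  if (1 - c0 * E * AF <= 0) {
    stop_degenerate("gen_closed_form_case: baseline coverage fully averts the cause ",
                    "(c0 * E * AF = 1)")
  }
  nmr0 <- 20
  births <- deaths * 1000 / nmr0
  dem <- demography(stats::setNames(c(births, births), c(2008, 2009)),
                    nmr0 = nmr0, u5mr0 = 2 * nmr0)
  cod <- cause_profile(c(target = 1), c(untouched = 1))
  iv <- intervention("iv01", name = "synthetic closed-form intervention",
                     period = "curative", age_bands = "neonatal",
                     effectiveness = E, affected_fractions = c(target = AF))
  cov <- coverage_series("iv01", stats::setNames(c(100 * c0, 100 * c1),
                                                 c(2008, 2009)))
  profile <- country_profile("closed-form case", dem, cod, list(iv), list(cov),
                             mode = "direct_entry")
  expected <- deaths * (c1 - c0) * E * AF / (1 - c0 * E * AF)
  list(profile = profile, expected = expected)
}
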