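# Scenario runners: evaluation, missed opportunity, universal scale-up,
# and the rate conversions.

test_that("evaluate on a flat profile is zero and on random profiles matches the oracle", {
  flat <- make_profile(list(
    list(id = "a", E = 0.5, AF = 0.8, band = "post", anchors_pct = c(40, 40))))
  expect_identical(evaluate(flat, 2008, 2014)$grand_total, 0)
  p <- gen_profile(synth_config(seed = 21, n_interventions = 3, n_causes = 2))
  expect_equal(evaluate(p, 2008, 2014)$grand_total,
               oracle_total_averted(p, 2008, 2014), tolerance = 1e-9)
})

test_that("risk channels appear in exactly one of the two analysis modes", {
  p <- gen_profile(synth_config(seed = 5))
  direct <- evaluate(p, 2008, 2014, mode = "direct_entry")
  ivonly <- evaluate(p, 2008, 2014, mode = "intervention_only")
  expect_true(all(c("stunting", "wasting") %in% names(direct$totals)))
  expect_false(any(c("stunting", "wasting") %in% names(ivonly$totals)))
})

test_that("missed opportunity excludes interventions at or above the threshold", {
  p <- make_profile(list(
    list(id = "low", E = 0.5, AF = 0.8, band = "post", anchors_pct = c(40, 40)),
    list(id = "high", E = 0.5, AF = 0.8, band = "post", anchors_pct = c(92, 92)),
    list(id = "edge", E = 0.5, AF = 0.8, band = "post", anchors_pct = c(90, 90))))
  mot <- missed_opportunity(p, 2014, threshold = 90, horizon = 5)
  expect_identical(mot$intervention_id, "low")     # 92 and exactly-90 excluded
  # every intervention at or above a low threshold: empty ranking
  mot40 <- missed_opportunity(p, 2014, threshold = 40)
  expect_identical(mot40$intervention_id, character(0))
  expect_error(missed_opportunity(p, 2014, horizon = 3), "at least 5")
})

test_that("missed opportunity accumulates the closed-form value over the horizon", {
  # single intervention at 0%, E=0.5, AF=1, 1000 annual cause deaths:
  # stepping to 90% saves 450/year, 2250 over 5 years
  p <- make_profile(list(list(id = "a", E = 0.5, AF = 1, band = "post",
                              anchors_pct = c(0, 0))),
                    births = 1e5 / 3, nmr0 = 30, u5mr0 = 60)
  mot <- missed_opportunity(p, 2014, threshold = 90, horizon = 5)
  expect_equal(mot$averted_1to59, 2250, tolerance = 1e-9)
  expect_equal(mot$averted_neonatal, 0)
})

test_that("a missed-opportunity row equals evaluate() on the single-change profile", {
  p <- gen_profile(synth_config(seed = 13, n_interventions = 4, n_causes = 3))
  mot <- missed_opportunity(p, 2014, threshold = 90, horizon = 5)
  id <- mot$intervention_id[1]
  # hand-build the equivalent two-anchor profile: everything frozen at 2014
  # values except `id`, stepped to 90 at 2015 and held
  p2 <- p
  p2$coverages <- lapply(p$coverages, function(s) {
    c14 <- 100 * interpolate_coverage(s, 2014)
    if (s$intervention_id == id) {
      coverage_series(id, c("2014" = c14, "2015" = 90))
    } else {
      coverage_series(s$intervention_id, c("2014" = c14))
    }
  })
  p2$risk_factors <- lapply(p$risk_factors, function(rf) {
    rf$prevalence_anchors <- stats::setNames(
      livesaved::interpolate_coverage(
        coverage_series("x", rf$prevalence_anchors), 2014) * 100, 2014)
    rf
  })
  ref <- evaluate(p2, 2014, 2019)
  expect_equal(mot$averted_total[1], ref$grand_total, tolerance = 1e-9)
})

test_that("ranking is by total deaths averted, descending, ties by id", {
  p <- make_profile(list(
    list(id = "big", E = 0.8, AF = 1, band = "post", anchors_pct = c(10, 10)),
    list(id = "a_twin", E = 0.5, AF = 0.5, band = "post", anchors_pct = c(30, 30)),
    list(id = "b_twin", E = 0.5, AF = 0.5, band = "post", anchors_pct = c(30, 30))))
  mot <- missed_opportunity(p, 2014)
  expect_identical(mot$intervention_id, c("big", "a_twin", "b_twin"))
  expect_true(all(diff(mot$averted_total) <= 1e-12))
})

test_that("universal scale-up reports target-minus-baseline increases", {
  p <- make_profile(list(
    list(id = "tt", E = 0.5, AF = 0.6, band = "neonatal", anchors_pct = c(86, 88)),
    list(id = "itn", E = 0.6, AF = 0.8, band = "post", anchors_pct = c(41.7, 70.9))))
  su <- universal_scaleup(p, 2008, 2014, target = 100)
  inc <- su$increases
  expect_equal(inc$increase[inc$intervention_id == "tt"], 14.0)
  expect_equal(inc$increase[inc$intervention_id == "itn"], 58.3)
  expect_gt(su$result$grand_total, 0)
  expect_error(universal_scaleup(p, 2008, 2014, target = 60),
               "below the maximum observed coverage")
})

test_that("scale-up to the existing endline anchors reproduces evaluate()", {
  p <- make_profile(list(
    list(id = "a", E = 0.5, AF = 0.8, band = "post", anchors_pct = c(20, 80)),
    list(id = "b", E = 0.4, AF = 0.6, band = "neonatal", anchors_pct = c(35, 80))))
  su <- universal_scaleup(p, 2008, 2014, target = 80)
  ev <- evaluate(p, 2008, 2014)
  expect_equal(su$result$grand_total, ev$grand_total, tolerance = 1e-12)
  expect_equal(su$result$ledger$averted, ev$ledger$averted, tolerance = 1e-12)
})

test_that("an intervention already at the target contributes zero lives saved", {
  p <- make_profile(list(
    list(id = "done", E = 0.7, AF = 0.9, band = "post", anchors_pct = c(100, 100)),
    list(id = "grow", E = 0.5, AF = 0.5, band = "post", anchors_pct = c(50, 70))))
  su <- universal_scaleup(p, 2008, 2014, target = 100)
  expect_equal(su$increases$increase[su$increases$intervention_id == "done"], 0)
  expect_identical(unname(su$result$totals[["done"]]), 0)
})

test_that("counterfactual rates invert the deaths arithmetic", {
  p <- make_profile(list(list(id = "a", E = 0.5, AF = 1, band = "post",
                              anchors_pct = c(0, 60))))
  d <- data.frame(year = c(2014, 2014),
                  age_band = c("neonatal", "1-59 months"),
                  deaths = c(2000, 3000))
  r <- counterfactual_rates(p, d)
  expect_equal(r$nmr, 20)
  expect_equal(r$u5mr, 50)
  # zero intervention effect reproduces the baseline rates
  flat <- make_profile(list(list(id = "a", E = 0.5, AF = 1, band = "post",
                                 anchors_pct = c(30, 30))))
  res <- evaluate(flat, 2008, 2014)
  expect_equal(res$rates$nmr, rep(flat$demography$nmr0, nrow(res$rates)),
               tolerance = 1e-12)
  expect_equal(res$rates$u5mr, rep(flat$demography$u5mr0, nrow(res$rates)),
               tolerance = 1e-12)
  # halving deaths halves rates
  d2 <- d; d2$deaths <- d$deaths / 2
  expect_equal(counterfactual_rates(p, d2)$u5mr, 25)
})

test_that("rates are invariant to relabelling causes", {
  mk <- function(causes) {
    dem <- demography(stats::setNames(rep(1e5, 2), c(2008, 2014)), 20, 50)
    cod <- cause_profile(c(neo = 1),
                         stats::setNames(c(0.4, 0.6), causes))
    iv <- intervention("a", period = "curative", age_bands = "1-59 months",
                       effectiveness = 0.5,
                       affected_fractions = stats::setNames(0.8, causes[1]))
    country_profile("perm", dem, cod, list(iv),
                    list(coverage_series("a", c("2008" = 10, "2014" = 70))))
  }
  r1 <- evaluate(mk(c("malaria", "pneumonia")), 2008, 2014)
  r2 <- evaluate(mk(c("cause_z", "cause_a")), 2008, 2014)
  expect_equal(r1$rates, r2$rates, tolerance = 1e-12)
  expect_equal(r1$grand_total, r2$grand_total, tolerance = 1e-12)
})

test_that("scenario specs validate and dispatch to the right runner", {
  expect_error(scenario_spec("missed_opportunity", 2014, horizon = 4),
               "at least 5")
  expect_error(scenario_spec("evaluate", 2014, 2010), "precede")
  p <- gen_profile(synth_config(seed = 2, n_interventions = 4, n_causes = 3))
  sp <- scenario_spec("evaluate", 2008, 2014)
  expect_equal(run_scenario(p, sp)$grand_total,
               evaluate(p, 2008, 2014)$grand_total)
  mot <- run_scenario(p, scenario_spec("missed_opportunity", 2014))
  expect_s3_class(mot, "mot_table")
})
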