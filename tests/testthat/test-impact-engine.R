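# The core deterministic model: interpolation, residuals, risk scaling,
# scenario deaths, attribution, and the engine-wide properties.

test_that("coverage interpolation is linear between anchors and clamps outside", {
  s <- coverage_series("itn", c("2008" = 41.7, "2014" = 70.9))
  expect_equal(interpolate_coverage(s, 2014), 0.709)
  expect_equal(interpolate_coverage(s, 2011), 0.563)  # midpoint
  expect_equal(interpolate_coverage(s, 2005), 0.417)  # clamp left
  expect_equal(interpolate_coverage(s, 2030), 0.709)  # clamp right
  s1 <- coverage_series("flat", c("2010" = 55))
  expect_equal(interpolate_coverage(s1, 2008), 0.55)
})

test_that("effective coverage is identity without herd, boosted and capped with", {
  expect_equal(effective_coverage(0.5), 0.5)
  h <- herd_spec(threshold = 0.8, max_boost = 0.1)
  expect_equal(effective_coverage(0.8, h), 0.8)   # boost starts at zero
  expect_equal(effective_coverage(1.0, h), 1.0)   # min(1, 1 * 1.1) capped
  # continuous and nondecreasing on a grid
  grid <- seq(0, 1, by = 0.01)
  vals <- effective_coverage(grid, h)
  expect_true(all(diff(vals) >= -1e-12))
  expect_true(all(vals >= grid - 1e-12 & vals <= 1))
})

test_that("residual factor multiplies active interventions and defaults to 1", {
  iv <- function(id, E, AF) {
    intervention(id, period = "curative", age_bands = "1-59 months",
                 effectiveness = E, affected_fractions = c(malaria = AF))
  }
  expect_equal(residual_factor(list(), numeric(0), "malaria", "1-59 months"), 1)
  expect_equal(
    residual_factor(list(iv("a", 1, 1)), c(a = 1), "malaria", "1-59 months"), 0)
  expect_equal(
    residual_factor(list(iv("a", 0.6, 0.5), iv("b", 0.6, 0.5)),
                    c(a = 0.5, b = 0.5), "malaria", "1-59 months"),
    0.85^2)
  # intervention on another band leaves the factor untouched
  expect_equal(
    residual_factor(list(iv("a", 0.6, 0.5)), c(a = 0.5), "malaria", "neonatal"), 1)
})

test_that("risk scaler is the population mean relative risk", {
  expect_equal(risk_scaler(0, 7), 1)
  expect_equal(risk_scaler(0.5, 3), 2)
  expect_equal(risk_scaler(0.086, 2), 1.086)
  # increasing in both arguments
  expect_true(risk_scaler(0.6, 2) > risk_scaler(0.5, 2))
  expect_true(risk_scaler(0.5, 3) > risk_scaler(0.5, 2))
  expect_error(risk_scaler(0.5, 0.8))
})

test_that("scenario deaths normalise to baseline and follow the residual ratio", {
  p <- make_profile(list(list(id = "a", E = 0.5, AF = 1, band = "post",
                              anchors_pct = c(0, 60))),
                    births = 1e5 / 3, nmr0 = 30, u5mr0 = 60)
  # post band has 1000 baseline deaths
  base_cov <- c(a = 0)
  unchanged <- cause_deaths_under_scenario(p, base_cov, year = 2008)
  expect_equal(unname(unchanged[["1-59 months"]][["post_cause"]]), 1000,
               tolerance = 1e-12)
  up <- cause_deaths_under_scenario(p, c(a = 0.6), year = 2008)
  expect_equal(unname(up[["1-59 months"]][["post_cause"]]), 700, tolerance = 1e-12)
  # decreasing coverage from a nonzero baseline raises deaths
  p2 <- make_profile(list(list(id = "a", E = 0.5, AF = 1, band = "post",
                               anchors_pct = c(60, 30))),
                     births = 1e5 / 3, nmr0 = 30, u5mr0 = 60)
  down <- cause_deaths_under_scenario(p2, c(a = 0.3), year = 2008)
  expect_equal(unname(down[["1-59 months"]][["post_cause"]]), 1000 * 0.85 / 0.7,
               tolerance = 1e-12)
  # full baseline aversion is degenerate and names the cause
  p3 <- make_profile(list(list(id = "a", E = 1, AF = 1, band = "post",
                               anchors_pct = c(100, 100))))
  expect_error(cause_deaths_under_scenario(p3, c(a = 1), year = 2008),
               "post_cause")
})

test_that("attribution sums exactly, zeroes unchanged channels, signs follow change", {
  # single changed channel takes the whole total
  a1 <- attribute_lives_saved(1000, c(a = 1), c(a = 0.7))
  expect_equal(unname(a1[["a"]]), 300, tolerance = 1e-12)
  # two identical changes split 50/50
  a2 <- attribute_lives_saved(1000, c(a = 0.9, b = 0.9), c(a = 0.8, b = 0.8))
  expect_equal(unname(a2[["a"]]), unname(a2[["b"]]))
  expect_equal(sum(a2), 1000 * (1 - (0.8 / 0.9)^2), tolerance = 1e-12)
  # unchanged channel receives exactly zero
  a3 <- attribute_lives_saved(1000, c(a = 0.9, b = 0.6), c(a = 0.7, b = 0.6))
  expect_identical(unname(a3[["b"]]), 0)
  # one up, one down: signed allocations summing to the brute-force net
  f0 <- c(up = 1 - 0 * 0.5, down = 1 - 0.6 * 0.5)
  f1 <- c(up = 1 - 0.6 * 0.5, down = 1 - 0.3 * 0.5)
  a4 <- attribute_lives_saved(1000, f0, f1)
  net <- 1000 * (1 - prod(f1) / prod(f0))
  expect_equal(sum(a4), net, tolerance = 1e-12)
  expect_gt(a4[["up"]], 0)
  expect_lt(a4[["down"]], 0)
  # exactly offsetting changes: continuous limit, zero-sum allocation
  a5 <- attribute_lives_saved(1000, c(a = 0.8, b = 0.5), c(a = 0.5, b = 0.8))
  expect_equal(sum(a5), 0, tolerance = 1e-9)
  expect_gt(a5[["a"]], 0)
})

test_that("one-intervention one-cause lives saved matches the closed form on a grid", {
  set.seed(402)
  for (i in 1:100) {
    c0 <- runif(1, 0, 0.9); c1 <- runif(1, 0, 1)
    E <- runif(1, 0.1, 0.9); AF <- runif(1, 0.1, 1)
    D <- runif(1, 100, 5000)
    cf <- gen_closed_form_case(c0, c1, E, AF, D)
    res <- lives_saved(cf$profile, 2008, 2009)
    expect_equal(res$grand_total, cf$expected, tolerance = 1e-9)
    expect_equal(unname(res$totals[["iv01"]]), cf$expected, tolerance = 1e-9)
  }
})

test_that("engine agrees with the brute-force oracle on small random profiles", {
  for (seed in 1:6) {
    p <- gen_profile(synth_config(seed = seed, n_interventions = 3, n_causes = 2))
    res <- lives_saved(p, 2008, 2014)
    expect_equal(res$grand_total, oracle_total_averted(p, 2008, 2014),
                 tolerance = 1e-9)
  }
})

test_that("no change means zero, increases are nonnegative, decreases nonpositive", {
  flat <- make_profile(list(
    list(id = "a", E = 0.5, AF = 0.8, band = "post", anchors_pct = c(40, 40)),
    list(id = "b", E = 0.4, AF = 0.5, band = "neonatal", anchors_pct = c(70, 70))))
  res <- lives_saved(flat, 2008, 2014)
  expect_identical(res$grand_total, 0)
  expect_true(all(res$ledger$averted == 0))

  mixed <- make_profile(list(
    list(id = "up", E = 0.5, AF = 0.8, band = "post", anchors_pct = c(20, 80)),
    list(id = "down", E = 0.4, AF = 0.5, band = "post", anchors_pct = c(60, 30)),
    list(id = "still", E = 0.9, AF = 0.9, band = "post", anchors_pct = c(50, 50))))
  r <- lives_saved(mixed, 2008, 2014)
  expect_gt(r$totals[["up"]], 0)
  expect_lt(r$totals[["down"]], 0)
  expect_identical(unname(r$totals[["still"]]), 0)
  expect_true(all(r$ledger$averted[r$ledger$channel == "down"] <= 0))
})

test_that("ledger conserves the joint deaths-averted and respects the baseline bound", {
  for (seed in c(2, 9)) {
    p <- gen_profile(synth_config(seed = seed, n_interventions = 8, n_causes = 4))
    res <- lives_saved(p, 2008, 2014)
    joint <- res$deaths$counterfactual_deaths - res$deaths$scenario_deaths
    # per (year, band): attributed allocations sum to the joint difference
    for (i in seq_len(nrow(res$deaths))) {
      cell <- res$ledger$averted[res$ledger$year == res$deaths$year[i] &
                                   res$ledger$age_band == res$deaths$age_band[i]]
      expect_equal(sum(cell), joint[i], tolerance = 1e-9 * max(1, abs(joint[i])))
    }
    # averted never exceeds the baseline deaths of the cell
    expect_true(all(joint <= res$deaths$counterfactual_deaths + 1e-9))
    expect_equal(res$grand_total, sum(joint), tolerance = 1e-9)
  }
})

test_that("lives saved is nondecreasing in a single endline coverage anchor", {
  base <- c(20, 40, 60)
  prev_total <- -Inf
  for (endline in c(30, 50, 70, 90)) {
    p <- make_profile(list(
      list(id = "a", E = 0.5, AF = 0.8, band = "post", anchors_pct = c(20, endline)),
      list(id = "b", E = 0.3, AF = 0.5, band = "post", anchors_pct = c(40, 55))))
    tot <- lives_saved(p, 2008, 2014)$grand_total
    expect_gt(tot, prev_total)
    prev_total <- tot
  }
})

test_that("direct-entry risk factors scale deaths by the mean-RR ratio", {
  # wasting-like decline 8.6% -> 4.7% with RR 2 on the post-band cause
  p <- make_profile(list(list(id = "a", E = 0.5, AF = 1, band = "post",
                              anchors_pct = c(30, 30))),
                    risk = list(name = "wasting", prev_pct = c(8.6, 4.7),
                                rr = c(post_cause = 2)))
  res <- lives_saved(p, 2008, 2014)
  expect_identical(unname(res$totals[["a"]]), 0)
  expect_gt(res$totals[["wasting"]], 0)
  expect_equal(res$grand_total, oracle_total_averted(p, 2008, 2014),
               tolerance = 1e-9)
})

test_that("mode selects exactly one risk pathway and credits the right channel", {
  dem <- demography(stats::setNames(rep(1e5, 2), c(2008, 2014)), 20, 50)
  cod <- cause_profile(c(neo = 1), c(malaria = 1))
  cf_iv <- intervention("feed", period = "preventive", age_bands = "1-59 months",
                        effectiveness = 0.2, affected_fractions = c(malaria = 0.1))
  other <- intervention("itn", period = "preventive", age_bands = "1-59 months",
                        effectiveness = 0.6, affected_fractions = c(malaria = 0.5))
  covs <- list(coverage_series("feed", c("2008" = 20, "2014" = 70)),
               coverage_series("itn", c("2008" = 40, "2014" = 40)))
  rf <- risk_factor("stunting", c("2008" = 30, "2014" = 20),
                    relative_risks = c(malaria = 2.5),
                    linked_interventions = c(feed = 0.3))
  mk <- function(mode) country_profile("m", dem, cod, list(cf_iv, other), covs,
                                       list(rf), mode = mode)
  direct <- lives_saved(mk("direct_entry"), 2008, 2014)
  indirect <- lives_saved(mk("intervention_only"), 2008, 2014)
  # direct entry: stunting channel present and positive, prevalence driven by anchors
  expect_true("stunting" %in% names(direct$totals))
  expect_gt(direct$totals[["stunting"]], 0)
  # intervention_only: no stunting channel; its effect flows through the link,
  # so the linked intervention earns more than its direct-AF pathway alone
  expect_false("stunting" %in% names(indirect$totals))
  no_rf <- mk("intervention_only")
  no_rf$risk_factors <- list()
  base_feed <- lives_saved(no_rf, 2008, 2014)$totals[["feed"]]
  expect_gt(indirect$totals[["feed"]], base_feed)
  # unchanged bystander stays at zero in both modes
  expect_identical(unname(direct$totals[["itn"]]), 0)
  expect_identical(unname(indirect$totals[["itn"]]), 0)
})
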