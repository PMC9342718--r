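# Scenario runners: baseline-to-endline evaluation, one-at-a-time
# missed-opportunity ranking, and universal scale-up.

#' Specify a scenario
#'
#' A small validated container naming which analysis to run and its
#' parameters; [run_scenario()] dispatches on `kind`.
#'
#' @param kind `"evaluate"`, `"missed_opportunity"`, or `"universal_scaleup"`.
#' @param t0,t1 Baseline and endline years (`t1` defaults to
#'   `t0 + horizon` for missed-opportunity runs).
#' @param threshold Missed-opportunity coverage threshold, percent (default
#'   90): interventions at or above it are excluded and the rest are stepped
#'   up to it.
#' @param target Universal scale-up coverage target, percent (default 100).
#' @param horizon Missed-opportunity horizon in years; at least 5 years are
#'   required to estimate impact.
#' @return An object of class `scenario_spec`.
#' @export
scenario_spec <- function(kind = c("evaluate", "missed_opportunity", "universal_scaleup"),
                          t0, t1 = NULL, threshold = 90, target = 100,
                          horizon = 5) {
  kind <- match.arg(kind)
  if (horizon < 5) {
    stop_validation("scenario_spec: horizon must be at least 5 years")
  }
  if (!(threshold > 0 && threshold <= 100) || !(target > 0 && target <= 100)) {
    stop_validation("scenario_spec: threshold and target must lie in (0,100]")
  }
  if (is.null(t1)) t1 <- t0 + horizon
  if (!(t0 < t1)) stop_validation("scenario_spec: t0 must precede t1")
  structure(list(kind = kind, t0 = t0, t1 = t1, threshold = threshold,
                 target = target, horizon = horizon),
            class = "scenario_spec")
}

#' Run a scenario specification against a profile
#'
#' @param profile A `country_profile`.
#' @param spec A [scenario_spec()].
#' @param ... Passed through to the underlying runner.
#' @return The runner's result ([evaluate()], [missed_opportunity()], or
#'   [universal_scaleup()]).
#' @export
run_scenario <- function(profile, spec, ...) {
  stopifnot(inherits(spec, "scenario_spec"))
  switch(spec$kind,
    evaluate = evaluate(profile, spec$t0, spec$t1, ...),
    missed_opportunity = missed_opportunity(profile, spec$t0,
                                            threshold = spec$threshold,
                                            horizon = spec$horizon, ...),
    universal_scaleup = universal_scaleup(profile, spec$t0, spec$t1,
                                          target = spec$target, ...))
}

#' Evaluate lives saved between a baseline and an endline year
#'
#' The headline analysis: coverages (and, in direct-entry mode, risk-factor
#' prevalences) are linearly interpolated from `t0` to `t1`, and deaths
#' averted relative to the held-at-`t0` counterfactual are accumulated and
#' attributed per channel. The result carries the per-channel ledger and the
#' scenario's counterfactual mortality rates.
#'
#' @param profile A `country_profile` spanning \[`t0`, `t1`\].
#' @param t0,t1 Baseline and endline years.
#' @param mode Analysis mode; defaults to the profile's.
#' @return A `lives_saved_result`; see [lives_saved()].
#' @export
evaluate <- function(profile, t0, t1, mode = profile$mode) {
  lives_saved(profile, t0, t1, mode = mode)
}

#' Missed-opportunity ranking at a coverage threshold
#'
#' For each intervention whose coverage at `base_year` is below `threshold`
#' percent, builds a scenario in which every channel is held at its
#' `base_year` value except that one intervention, which is stepped up to the
#' threshold at `base_year + 1` and held there, and accumulates deaths
#' averted over `horizon` years split by age band. Interventions at or above
#' the threshold are excluded. Rows are sorted by total deaths averted,
#' descending, with ties broken by intervention id.
#'
#' @param profile A `country_profile`.
#' @param base_year Year whose coverages define the baseline.
#' @param threshold Coverage threshold, percent (default 90).
#' @param horizon Accumulation horizon in years (default 5, the minimum).
#' @return A data frame of class `mot_table` with columns `intervention_id`,
#'   `name`, `baseline_coverage` (percent), `averted_neonatal`,
#'   `averted_1to59`, `averted_total`.
#' @export
missed_opportunity <- function(profile, base_year, threshold = 90, horizon = 5) {
  stopifnot(inherits(profile, "country_profile"))
  if (horizon < 5) {
    stop_validation("missed_opportunity: horizon must be at least 5 years")
  }
  covs_pct <- 100 * coverage_map(profile, base_year)
  eligible <- names(covs_pct)[covs_pct < threshold]
  iv_names <- stats::setNames(
    vapply(profile$interventions, `[[`, "", "name"),
    vapply(profile$interventions, `[[`, "", "id"))

  rows <- lapply(eligible, function(id) {
    p2 <- freeze_profile(profile, base_year)
    k <- match(id, vapply(p2$coverages, `[[`, "", "intervention_id"))
    p2$coverages[[k]] <- coverage_series(
      id, stats::setNames(c(covs_pct[[id]], threshold),
                          c(base_year, base_year + 1)))
    res <- lives_saved(p2, base_year, base_year + horizon)
    by_band <- tapply(res$ledger$averted, res$ledger$age_band, sum)
    data.frame(intervention_id = id, name = iv_names[[id]],
               baseline_coverage = covs_pct[[id]],
               averted_neonatal = as.numeric(by_band[["neonatal"]]),
               averted_1to59 = as.numeric(by_band[["1-59 months"]]),
               stringsAsFactors = FALSE)
  })
  out <- if (length(rows)) {
    do.call(rbind, c(rows, list(make.row.names = FALSE)))
  } else {
    data.frame(intervention_id = character(0), name = character(0),
               baseline_coverage = numeric(0),
               averted_neonatal = numeric(0), averted_1to59 = numeric(0))
  }
  out$averted_total <- out$averted_neonatal + out$averted_1to59
  out <- out[order(-out$averted_total, out$intervention_id), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mot_table", "data.frame")
  attr(out, "threshold") <- threshold
  attr(out, "horizon") <- horizon
  attr(out, "base_year") <- base_year
  out
}

# Hold every coverage series and prevalence series flat at `year`.
freeze_profile <- function(profile, year) {
  profile$coverages <- lapply(profile$coverages, function(s) {
    coverage_series(s$intervention_id,
                    stats::setNames(100 * interpolate_coverage(s, year), year))
  })
  profile$risk_factors <- lapply(profile$risk_factors, function(rf) {
    rf$prevalence_anchors <- stats::setNames(
      interp_anchors(rf$prevalence_anchors, year), year)
    rf
  })
  profile
}

#' Universal scale-up of every intervention to a target coverage
#'
#' Replaces every intervention's endline anchor with `target` percent,
#' interpolates linearly from the `t0` coverages, and evaluates lives saved
#' over \[`t0`, `t1`\]. Alongside the ledger it reports each intervention's
#' coverage increase (`target - coverage(t0)`, percentage points) and the
#' counterfactual neonatal and under-five mortality rates under the scaled-up
#' scenario.
#'
#' @param profile A `country_profile`.
#' @param t0,t1 Baseline and endline years.
#' @param target Target coverage, percent; must be at least the largest
#'   observed coverage (default 100).
#' @return A list of class `scaleup_result`: `result` (a
#'   `lives_saved_result`), `increases` (data frame: intervention_id, name,
#'   baseline_coverage, increase), and `rates` (data frame: year, nmr, u5mr
#'   under the scenario).
#' @export
universal_scaleup <- function(profile, t0, t1, target = 100) {
  stopifnot(inherits(profile, "country_profile"))
  covs0_pct <- 100 * coverage_map(profile, t0)
  max_obs <- max(vapply(profile$coverages, function(s) max(s$anchors), numeric(1)))
  if (target < max_obs) {
    stop_validation("universal_scaleup: target (", target,
                    ") below the maximum observed coverage (", max_obs, ")")
  }
  p2 <- profile
  p2$coverages <- lapply(profile$coverages, function(s) {
    coverage_series(s$intervention_id,
                    stats::setNames(c(covs0_pct[[s$intervention_id]], target),
                                    c(t0, t1)))
  })
  res <- lives_saved(p2, t0, t1)
  iv_names <- stats::setNames(
    vapply(profile$interventions, `[[`, "", "name"),
    vapply(profile$interventions, `[[`, "", "id"))
  increases <- data.frame(
    intervention_id = names(covs0_pct),
    name = iv_names[names(covs0_pct)],
    baseline_coverage = round_half_away(as.numeric(covs0_pct), 1),
    increase = round_half_away(target - as.numeric(covs0_pct), 1),
    stringsAsFactors = FALSE)
  rownames(increases) <- NULL
  structure(list(result = res, increases = increases, rates = res$rates),
            class = "scaleup_result")
}

#' Mortality rates implied by a deaths ledger
#'
#' Converts deaths per year and age band back to the mortality-rate scale:
#' `NMR = neonatal deaths / births * 1000` and
#' `U5MR = (neonatal + 1-59-month deaths) / births * 1000`.
#'
#' @param profile A `country_profile` (supplies the births series).
#' @param deaths_by_band_year Data frame with columns `year`, `age_band`, and
#'   a deaths column (the first remaining numeric column is used).
#' @return Data frame with columns `year`, `nmr`, `u5mr`.
#' @export
counterfactual_rates <- function(profile, deaths_by_band_year) {
  stopifnot(inherits(profile, "country_profile"),
            all(c("year", "age_band") %in% names(deaths_by_band_year)))
  dcol <- setdiff(names(deaths_by_band_year), c("year", "age_band"))[1]
  years <- sort(unique(deaths_by_band_year$year))
  out <- lapply(years, function(y) {
    births <- interp_anchors(profile$demography$live_births, y)
    d <- deaths_by_band_year[deaths_by_band_year$year == y, ]
    neo <- sum(d[d$age_band == "neonatal", dcol])
    post <- sum(d[d$age_band == "1-59 months", dcol])
    data.frame(year = y, nmr = neo / births * 1000,
               u5mr = (neo + post) / births * 1000)
  })
  do.call(rbind, out)
}

#' @export
print.mot_table <- function(x, ...) {
  cat("Missed-opportunity ranking (threshold ", attr(x, "threshold"),
      "%, horizon ", attr(x, "horizon"), " years from ",
      attr(x, "base_year"), ")\n", sep = "")
  df <- as.data.frame(x)
  df$averted_neonatal <- round_half_away(df$averted_neonatal)
  df$averted_1to59 <- round_half_away(df$averted_1to59)
  df$averted_total <- round_half_away(df$averted_total)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
print.scaleup_result <- function(x, ...) {
  cat("Universal scale-up\n")
  cat("  lives saved:", format_count(x$result$grand_total), "\n")
  last <- x$rates[which.max(x$rates$year), ]
  cat("  endline scenario rates: NMR ", round_half_away(last$nmr, 1),
      ", U5MR ", round_half_away(last$u5mr, 1), " per 1,000 live births\n",
      sep = "")
  invisible(x)
}
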