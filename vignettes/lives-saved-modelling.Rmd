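---
title: "Deterministic lives-saved modelling of under-five mortality"
author: "livesaved authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deterministic lives-saved modelling of under-five mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(livesaved)
```

## The model

`livesaved` implements the deterministic attribution model behind
lives-saved analyses of child-health programmes. The question it answers:
given a country's births, baseline mortality, cause-of-death structure, and
the coverage trajectories of a portfolio of interventions, how many
under-five deaths did each intervention avert relative to a world where
coverage had stayed at its baseline level — and which interventions would
avert the most if scaled up?

Deaths are modelled in two age bands, neonatal (first month) and 1–59
months, because intervention biology differs sharply across that boundary.
Baseline expected deaths come from the cohort-synthetic approximation

$$D_{\text{neo}}(t) = B(t)\,\frac{\mathrm{NMR}_0}{1000},\qquad
  D_{\text{post}}(t) = B(t)\,\frac{\mathrm{U5MR}_0-\mathrm{NMR}_0}{1000},$$

with $B(t)$ the exogenous live-births series, and are split across causes by
fixed per-band fractions. A full life table (competing exposure ages, cohort
carry-over between years) is deliberately not implemented: the model's
inputs are the two headline rates, and the approximation keeps every
quantity auditable by hand. Consequently lives saved are counted for deaths
*occurring* within the analysis span; birth cohorts that enter the
under-five population before the baseline year are not tracked separately.

### Interventions

Each intervention $i$ has an effectiveness $E_i \in [0,1]$ and, per cause
$k$, an affected fraction $AF_{ik}$ — the fraction of that cause's mortality
amenable to the intervention. At coverage $c_i$ the single-intervention
impact is the standard product $c_i E_i AF_{ik}$. Interventions acting on
the same cause combine multiplicatively through residuals:

$$R_k(t) = \prod_{i} \bigl(1 - c_i(t)\,E_i\,AF_{ik}\bigr),$$

the fraction of cause-$k$ deaths *not* averted. The multiplicative form is
the standard convention for this family of tools; it guarantees that no
stack of interventions can avert more than 100% of a cause, which additive
impact would violate for large portfolios.

Coverage is stored in percent, exactly as survey tables print it, and is
interpolated linearly between anchor years (the typical data situation is
two anchors, a baseline and an endline survey). Queries outside the
anchored span clamp to the nearest anchor. The percent→proportion
conversion happens exactly once, in `interpolate_coverage()`.

### Counterfactual and sign semantics

Scenario deaths for year $t$ are normalised against the *same year's*
deaths with every channel held at its baseline-year value:

$$D_k(t) = D^{0}_k(t)\,\frac{R_k(t)}{R_k(t_0)}
           \prod_r \frac{\rho_{rk}(t)}{\rho_{rk}(t_0)}.$$

Holding everything at $t_0$ therefore reproduces baseline deaths exactly:
no change in coverage means zero lives saved, a coverage increase means a
nonnegative number, and a coverage decline produces negative lives saved
(excess deaths) — the population that needed protection was less covered at
the endline than at the baseline. Because the counterfactual is recomputed
for every year, children already saved by a coverage change are not
re-saved in later years by the same change; this stands in for the "previous
lives saved" adjustment without multi-year cohort tracking, which is out of
scope.

### Risk factors

Stunting and wasting enter through the population mean relative risk at
prevalence $P$: $\rho(P) = P \cdot RR + (1-P)$, applied per cause as the
ratio $\rho(P(t))/\rho(P(t_0))$. Two mutually exclusive modes prevent
double counting:

* **direct_entry** — measured prevalence anchors drive the risk channels,
  which appear in the ledger under their own names ("stunting", "wasting");
  nutrition interventions linked to them have no prevalence effect.
* **intervention_only** — prevalence follows the linked interventions:
  $P(t) = P(t_0)\prod_\ell (1-c_\ell(t)e_\ell)/(1-c_\ell(t_0)e_\ell)$ with
  link efficacy $e_\ell$, and the risk-channel impact is credited to those
  interventions.

This mirrors the convention in published tables where the
complementary-feeding rows and the stunting/wasting rows are marked
not-applicable in complementary columns.

### Attribution

The per-year, per-cause deaths averted are a joint quantity; printed tables
nevertheless report one number per intervention. The package allocates by
**signed log-residual shares**: with per-channel factors $f_i$ (residual
terms for interventions, $\rho$ for risk channels), channel $i$ receives

$$\text{averted} \times \frac{w_i}{\sum_j w_j},\qquad
  w_i = \ln f_i(t_0) - \ln f_i(t).$$

The scheme is order-independent (sequential attribution, the obvious
alternative, depends on an arbitrary intervention ordering and was rejected
for irreproducibility), sums *exactly* to the joint total, gives exactly
zero to unchanged channels, reduces to the closed form for a single
channel, and hands negative allocations to channels whose coverage fell.
When the weights cancel exactly (offsetting changes, zero net) the
continuous limit $D_0 w_i$ is used, so attribution is continuous in the
inputs. Note that the allocation rule used inside the original tool is not
published; per-channel magnitudes from different rules legitimately differ
even when the joint total agrees.

For one intervention on one cause the whole machinery collapses to

$$\text{lives saved} = D_0\,\frac{(c_1-c_0)\,E\,AF}{1-c_0\,E\,AF},$$

which `gen_closed_form_case()` exposes as an analytic oracle; the test
suite verifies the engine against it on a 100-point random parameter grid,
and against an independent brute-force evaluation (direct multiplication of
both scenarios' residual products) on small random profiles, both to 1e-9
relative.

### Herd effects

Vaccines and bed nets protect non-covered children at high coverage. The
functional form of this adjustment is not published; the package's opt-in
implementation boosts effective coverage piecewise linearly above a
threshold,
$c_{\text{eff}} = \min\!\bigl(1,\; c\,(1 + b\,\max(0, c-\tau)/(1-\tau))\bigr)$,
continuous and nondecreasing, equal to $c$ at or below $\tau$. Herd
modelling defaults to **off** for every intervention; it is enabled per
intervention by attaching a `herd_spec(threshold, max_boost)`.

## Scenarios

* `evaluate(profile, t0, t1, mode)` — the headline evaluation: linear
  coverage scale-up between the anchors, annual steps, full ledger.
* `missed_opportunity(profile, base_year, threshold = 90, horizon = 5)` —
  every intervention below the threshold is individually stepped to it one
  year after the base year and held; deaths averted accumulate over the
  horizon, split by age band. Eligibility is strictly `< threshold`
  (interventions at or above it are excluded), and the threshold is an
  argument because published rankings occasionally include rows at or above
  the nominal cutoff. A minimum horizon of five years is enforced — the
  shortest span over which impact estimates are considered meaningful.
  Rows are ordered by total deaths averted, descending, ties broken by
  intervention id: a deterministic rule, documented here because published
  tables do not state theirs.
* `universal_scaleup(profile, t0, t1, target = 100)` — every endline anchor
  is replaced by the target, coverage is re-interpolated from the t0
  anchors, and the result carries each intervention's coverage increase
  (`target − coverage(t0)`) plus the counterfactual NMR/U5MR implied by the
  scenario deaths.

Annual time stepping is used throughout; a coverage change within a year
acts for that whole year.

## The synthetic generator

No national effectiveness/affected-fraction database is published, so the
package generates profiles with *known* ground truth instead of attempting
to reverse-engineer real ones. `gen_profile(synth_config(seed))` emulates
the structure of a national database: interventions cycle through six
delivery periods (pregnancy, childbirth, breastfeeding, preventive,
vaccine, curative) whose templates fix the age bands they act on and the
coverage range their baseline anchors are drawn from — vaccines start high
(50–95%), curative and preventive care lower (0–80%) — with two coverage
anchors six years apart (2008/2014 by default) and endline changes drawn
from −15 to +40 percentage points, so regressing programmes occur. Each
intervention touches 1–2 causes (sparse affected fractions, as in real
databases) with effectiveness in [0.2, 0.9]. Defaults describe a
high-mortality setting: NMR 31.2 and U5MR 75.3 per 1,000 live births,
850,000 births growing 2% a year — roughly a mid-2010s West African birth
cohort. Stunting and wasting carry relative risks in [1.5, 4] on the
infectious causes (malaria, pneumonia, diarrhoea), prevalences of 20–35%
and 5–12% respectively, declining over the span.

The generator seeds a local RNG per call and restores global state, so
fixtures are bit-reproducible and test order cannot matter.

What the generator does **not** emulate: real effectiveness values (its
values are labelled synthetic), survey measurement error, coverage data
gaps and assumption-filled series, subnational heterogeneity, or secular
cause-structure drift. Passing tests on synthetic profiles therefore
demonstrate the *arithmetic* of the engine, not the realism of any
particular country estimate — the packaged evaluation tables play that
role for the reporting arithmetic only, since the database behind their
engine runs is unpublished.

## Numerical choices

* Deaths are real-valued throughout; rounding (nearest, ties away from
  zero — the convention that reproduces every printed cell checked) happens
  only in reporting: integers for lives saved, one decimal for shares and
  rates.
* Percentage shares are computed from unrounded channel values against the
  unrounded total, then rounded.
* A cause fully averted at baseline ($R_k(t_0)=0$) is a degenerate input
  and raises an error naming the cause, as does an attribution call whose
  weights sum to zero while the total does not (impossible under the
  residual model, guarded regardless).
* Cause fractions must sum to 1 within 1e-9 per band; ledger conservation
  is asserted to 1e-9 relative in the tests.
* Profile files round-trip exactly: numerics are written with 17
  significant digits.

## Worked example

```{r example}
p <- gen_profile(synth_config(seed = 7))
res <- evaluate(p, 2008, 2014)
res

mot <- missed_opportunity(p, 2014, threshold = 90, horizon = 5)
head(as.data.frame(mot), 3)

su <- universal_scaleup(p, 2008, 2014, target = 100)
su
```

Problem sizes in the shipped tests mirror this vignette: portfolios of 3–20
interventions over 6–7 causes and a 6-year span, 100-point oracle grids,
and 5-year missed-opportunity horizons — ample to exercise every code path
while keeping any single run well under a second.

## Limitations

* The cohort-synthetic deaths conversion ignores life-table structure; the
  model is not a demographic projection (no fertility, family-planning, or
  HIV modules — births are an input).
* Effectiveness is assumed constant over time and space; quality of care is
  not modelled.
* The attribution rule, while exact-summing and order-independent, is one
  defensible choice among several; per-channel magnitudes are
  rule-dependent.
* No uncertainty intervals: the model is deterministic, as is the tool
  family it mirrors.
* Feasibility and cost of scale-up scenarios are out of scope.
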