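# livesaved

Deterministic lives-saved and missed-opportunity modelling of under-five
mortality, for epidemiologists and health-policy analysts who need to
attribute changes in child mortality to individual interventions — and to
rank the interventions whose scale-up would avert the most deaths next.

## The model

Expected deaths are computed in two age bands from an exogenous live-births
series and the baseline neonatal and under-five mortality rates
(`D_neo = B·NMR₀/1000`, `D_post = B·(U5MR₀−NMR₀)/1000`), split across
causes by fixed fractions. Each intervention *i* carries an effectiveness
*Eᵢ* and per-cause affected fractions *AFᵢₖ*; at coverage *cᵢ* the fraction
of cause-*k* deaths left unaverted is the multiplicative residual

```
R_k(t) = ∏ᵢ (1 − cᵢ(t)·Eᵢ·AFᵢₖ)
```

Scenario deaths are normalised against the same year with every channel
held at its baseline value, so zero coverage change means exactly zero
lives saved and coverage declines yield negative lives saved (excess
deaths). Stunting and wasting scale the infectious causes via the
population mean relative risk `ρ(P) = P·RR + (1−P)`, driven either by
measured prevalence ("direct entry") or by linked nutrition interventions —
never both. Deaths averted are attributed per intervention by signed
log-residual shares, an order-independent, exact-summing allocation that
reduces to the closed form
`D₀·(c₁−c₀)·E·AF / (1 − c₀·E·AF)` for a single channel.

Three scenario runners cover the standard analyses: `evaluate()`
(baseline→endline with linear coverage interpolation),
`missed_opportunity()` (each intervention below a coverage threshold —
default 90% — individually stepped to it and held over a ≥5-year horizon),
and `universal_scaleup()` (every endline anchor raised to a target, default
100%, with counterfactual NMR/U5MR).

The package also ships, as plain-text fixtures, the printed tables of a
published Ghana 2008–2014 evaluation (`load_fixture()`), and a seeded
synthetic country-profile generator (`gen_profile()`) with closed-form
ground truth (`gen_closed_form_case()`), since the effectiveness database
behind real national runs is not published.

## Worked example

```r
library(livesaved)

p <- gen_profile(synth_config(seed = 7))   # 20 interventions, 6 causes/band
res <- evaluate(p, 2008, 2014)
res
#> Lives-saved evaluation (direct_entry), 2008 -> 2014
#>   grand total: 43,031 deaths averted
#>   leading channels:
#>     stunting                            6,959 (16.2%)
#>     iv02                                6,705 (15.6%)
#>     iv12                                5,506 (12.8%)
#>     wasting                             4,261 (9.9%)
#>     iv11                                3,707 (8.6%)
```

43,031 is the total of deaths averted over 2009–2014 relative to holding
every coverage and prevalence at its 2008 value; the per-channel lines are
each channel's exact-summing share of that total (here the decline in
stunting prevalence is the largest single contributor). The same object
carries the full `(channel, year, age band)` ledger, scenario vs
counterfactual deaths, and the implied mortality rates.

```r
head(as.data.frame(missed_opportunity(p, 2014, threshold = 90)), 3)
#>   intervention_id                                 name baseline_coverage
#> 1            iv06    synthetic curative intervention 6          33.09456
#> 2            iv10 synthetic preventive intervention 10          53.82786
#> 3            iv18   synthetic curative intervention 18          53.97142
#>   averted_neonatal averted_1to59 averted_total
#> 1            0.000     10622.067     10622.067
#> 2            0.000      7750.533      7750.533
#> 3         5986.945         0.000      5986.945
```

Each row answers: if only this intervention were scaled from its 2014
coverage to 90% in 2015 and held, how many deaths would be averted by 2019,
in each age band?

Fixture arithmetic reproduces the printed tables exactly:

```r
t1 <- load_fixture("table1")
aggregate_fixture(t1, "lives_saved_direct")
#> [1] 48084
keep <- !is.na(t1$lives_saved_direct)
st <- shares(setNames(t1$lives_saved_direct, t1$intervention)[keep])
st[grepl("ITN/IRS", st$channel), ]
#> Insecticide-treated net/indoor residual spraying (ITN/IRS)      6,437(13.4)
#> Total                                             48,084(100)
```

A thin command-line front end over the same functions is installed at
`inst/cli/livesaved.R` (subcommands `evaluate`, `mot`, `scaleup`,
`fixtures`, `synth`).

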