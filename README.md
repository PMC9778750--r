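# ricerisk

Probabilistic human-health risk assessment of inorganic arsenic (iAs) in
rice, for exposure scientists and food-safety analysts. Rice accumulates
iAs — a Group 1 carcinogen — more than any other staple crop, and in
populations eating rice daily the resulting chronic dose is a public-health
question. `ricerisk` implements the full desk pipeline: fit a parametric
distribution to measured iAs concentrations, propagate it through
age-stratified dose and risk equations by Monte Carlo simulation, and ask
what regulatory interventions (maximum contaminant levels, supply
substitution, age-based exclusions) would buy in risk reduction.

## The model

For age group *j* with ingestion rate *IR_j* (g raw rice/day), body weight
*BW_j* (kg), exposure frequency *EF_j* (days/year) and exposure duration
*ED_j* (years), the average daily dose from a concentration *C* (ng iAs/g,
converted to mg/g by the single factor 10⁻⁶) is

    ADD_j = (C × 10⁻⁶ × IR_j × ED_j × EF_j) / (BW_j × AT_j),   AT_j = ED_j × 365 d

so ED_j cancels and ADD_j is in mg/kg-day. Cancer and non-cancer risk
weight each group by its share of the lifetime *LT* (70 y):

    ILCR = Σ_j ADD_j × SF × ED_j / LT          (slope factor SF = 1.5 (mg/kg-day)⁻¹)
    HQ   = Σ_j (ADD_j / RfD) × ED_j / LT       (reference dose RfD = 0.003 mg/kg-day)

Concentration uncertainty enters by sampling *C* from a distribution fitted
to the data (normal / lognormal / exponential, maximum likelihood, lowest
AIC selected; normal sampling is zero-truncated because concentrations are
physical). Each Monte Carlo iteration draws one *C* shared by all age
groups; 100,000 iterations by default. Because the equations are linear in
*C*, the mean ILCR equals the closed-form ILCR at the distribution mean —
an identity the test suite uses as an oracle.

## Worked example

```r
library(ricerisk)

ds    <- generate_concentration_data(seed = 1)          # synthetic survey
white <- dplyr::filter(ds, rice_type == "white")
fits  <- fit_concentration(white$ias_ng_g)
tidy(fits)
#>   family         param1 param2     n log_likelihood   aic selected
#> 1 normal      101.      44.8      64          -334.  672. TRUE
#> 2 lognormal     4.46     0.714    64          -355.  713. FALSE
#> 3 exponential   0.00992 NA        64          -359.  721. FALSE

tbl <- generate_exposure_table()                        # 27 age bins, EF = 6/7 × 365
rs  <- simulate_risk(select_best(fits), tbl, risk_constants(),
                     simulation_config(100000, seed = 1))
rs
#> <risk_summary: normal concentration model, 100000 iterations>
#>   lifetime ILCR: mean 4.192e-04, p95 7.153e-04
#>   lifetime HQ:   mean 9.315e-02, p95 1.590e-01  (below 1)

run_scenarios(list(scenario_mcl("MCL 100 ng/g", 100),
                   scenario_mcl("MCL 50 ng/g", 50),
                   scenario_exclude_ages("No rice <= 6 y", 6)), rs, white)
#>         scenario n_retained    ilcr_mean reduction_pct
#> 1   MCL 100 ng/g         34 0.0002826592      32.56537
#> 2    MCL 50 ng/g          6 0.0001328519      68.30523
#> 3 No rice <= 6 y         NA 0.0003473876      17.12298
```

The fit table says a normal model (mean ≈ 101, sd ≈ 45 ng/g) describes
white-rice iAs best by AIC. The lifetime incremental cancer risk of
≈ 4 × 10⁻⁴ means roughly 4 extra cancer cases per 10,000 lifelong
consumers under these exposure factors; the hazard quotient below 1 says
non-cancer effects are not expected. Imposing a 50 ng/g MCL — discarding
the 58 of 64 samples above it and refitting — would cut the mean ILCR by
about two thirds; exempting children up to age 6 removes the young bins'
share (here ≈ 17%).

A thin command-line wrapper over the same functions ships at
`inst/cli/rice-risk.R` (subcommands `generate-data`, `fit`, `assess`,
`scenarios`).

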