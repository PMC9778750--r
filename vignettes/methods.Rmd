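---
title: "Methods: probabilistic iAs-in-rice risk assessment"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: probabilistic iAs-in-rice risk assessment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ricerisk)
```

## The exposure model and its assumptions

`ricerisk` estimates chronic dietary exposure to inorganic arsenic (iAs)
from rice with the standard average-daily-dose framework. For age group
$j$,

$$ADD_j = \frac{C \times 10^{-6} \times IR_j \times ED_j \times EF_j}
               {BW_j \times AT_j}, \qquad AT_j = ED_j \times 365,$$

with $C$ in ng iAs per g raw rice, $IR_j$ the ingestion rate (g/day),
$EF_j$ the exposure frequency (days/year), $BW_j$ body weight (kg) and
$ED_j$ the years spent in the bin. Two modelling commitments deserve
emphasis:

* **Averaging time is $ED_j \times 365$, not lifetime.** The exposure
  duration therefore cancels inside $ADD_j$; the lifetime weighting enters
  only through the $ED_j/LT$ factor of the risk sums below. Packages and
  spreadsheets differ on this point and the two conventions differ by a
  factor $LT/ED_j$ per bin, so `compute_add()` documents and tests the
  cancellation explicitly.
* **One unit conversion, in one place.** Concentration data are in ng/g
  while the dose equation needs mg/g. The $10^{-6}$ factor is applied in
  `compute_add()` and nowhere else, so the class of factor-of-10 unit bugs
  that plagues risk spreadsheets has exactly one audit point.

Cancer and non-cancer risk aggregate the per-group terms:

$$ILCR = \sum_j ADD_j \cdot SF \cdot \frac{ED_j}{LT}, \qquad
  HQ = \sum_j \frac{ADD_j}{RfD} \cdot \frac{ED_j}{LT}.$$

Both sums are linear in $C$ and share every factor except $SF$ versus
$1/RfD$, so for any concentration distribution the identity
$ILCR = HQ \times SF \times RfD$ holds exactly on means when the same
draws feed both — the engine computes both sides from one draw vector and
the test suite asserts the identity to $10^{-12}$ relative. (Published
risk tables that violate this identity contain an internal inconsistency;
the engine cannot reproduce such tables and does not try.)

## Constants and tunable parameters

| Parameter | Unit | Default | Rationale |
|---|---|---|---|
| slope factor $SF$ | (mg/kg-day)$^{-1}$ | 1.5 | EPA oral potency for iAs |
| reference dose $RfD$ | mg/kg-day | 0.003 | EPA chronic oral RfD for iAs |
| lifetime $LT$ | years | 70 | conventional lifetime for ILCR |
| iterations | — | 100,000 | Monte Carlo error on the mean $\approx \sigma_C/316$, far below reporting precision |
| percentiles | — | 50, 95 | the mean/95th-percentile pair customary in dietary risk tables |
| exposure frequency $EF$ | days/year | $365 \times 6/7 = 312.857\ldots$ | rice eaten six days a week in a rice-staple diet |

All are overridable (`risk_constants()`, `simulation_config()`,
`generate_exposure_table()`).

## Distribution fitting

`fit_concentration()` fits normal, lognormal and exponential models by
closed-form maximum likelihood: normal mean and sd with the MLE divisor
$n$; lognormal mean and MLE-sd of the log values; exponential rate
$1/\bar{x}$. AIC is $2k - 2\ell$ with $k = 2, 2, 1$ free parameters and
`select_best()` takes the minimum; exact AIC ties break by the fixed
order normal, lognormal, exponential, so selection is deterministic.
Descriptive statistics (`concentration_stats()`) report the sample
($n-1$) standard deviation; the two conventions are surfaced separately
and never mixed. Values $\le 0$ are excluded from the lognormal fit only
(with a logged count): concentrations are physically positive and a
censored-data likelihood is out of scope. The closed forms are
cross-checked in the tests against `fitdistrplus`, an independent MLE
implementation.

## Sampling conventions

* **Zero truncation.** Normal concentration models are sampled with
  rejection at zero by default (`truncate_at_zero`): a fitted
  Normal(30.55, 16.85), for instance, carries about 3.5% negative mass
  that is physically meaningless. The truncation shifts the mean upward
  by $\sigma\,\phi(\mu/\sigma)/\Phi(\mu/\sigma)$; `distribution_mean()`
  implements that closed form and the tests verify it against numerical
  integration. The flag and the number of rejected draws are recorded in
  report metadata.
* **Lognormal parameter conventions.** A lognormal can be parameterised
  by the mean/sd of log values (log-scale, the statistical convention) or
  by the arithmetic mean/sd of the values themselves. Conflating the two
  is a recurrent pitfall in risk assessment: feeding log-scale parameters
  $(\mu, \sigma) = (4.1, 0.9)$ to a sampler that expects arithmetic
  moments collapses the distribution mean from
  $e^{4.1 + 0.405} \approx 90$ ng/g to $4.1$ ng/g — a 22-fold
  understatement of risk. `sample_concentrations()` defaults to the
  correct `log_scale` reading and offers `arithmetic` as an explicit
  compatibility mode; the acceptance tests demonstrate both behaviours so
  the contrast is documented, not silent.
* **Shared draw per iteration.** Each Monte Carlo iteration draws one
  concentration applied to all age groups: an iteration represents a
  lifetime lived under one long-run mean concentration. Full
  within-iteration correlation affects percentiles (they are the
  percentiles of lifetime risk, not of independent per-bin risks) but not
  means, by linearity. An independent-draws-per-group mode is out of
  scope.
* **Percentile estimator.** Linear interpolation between order statistics
  (`quantile()` type 7), so any percentile is bit-reproducible given a
  seed.
* **Seeding.** Every stochastic operation derives child seeds
  deterministically from the top-level seed, so adding or reordering
  pipeline stages cannot perturb the draws of other stages, and reruns
  with one seed are bit-identical.

## Mitigation scenarios

Three intervention kinds (`run_scenario()`), all evaluated against a
baseline run with identical table, constants and configuration so the
reduction isolates the intervention:

* **MCL filter** — remove samples above the limit, refit, re-simulate.
  The refit is forced to the baseline's selected family: small filtered
  datasets (an MCL of 50 ng/g can leave single-digit sample counts) would
  otherwise flip family on noise, and the reported scenario parameters
  stay comparable with the baseline's.
* **Substitute distribution** — swap in a known fitted model (a low-iAs
  farm subgroup or rice variety).
* **Age exclusion** — zero the ingestion rate of bins with
  `age_start < max_excluded_age + 1`, so excluding "up to 6 years"
  zeroes the bins from "<1" through "6". Age-boundary phrasing is
  genuinely ambiguous ("≤ 6 years of age" can mean before the 6th or the
  7th birthday); the implemented rule is a documented convention and the
  exclusion's reduction is tested against the exact identity that it must
  equal the zeroed bins' share of baseline risk under shared draws.

Reductions are ratios of mean ILCRs, and because ILCR is linear in $C$
the exposure-table factors cancel: substitution and MCL reductions are
invariant to the table (a tested property). That invariance is what makes
scenario reductions reproducible desk-side even when the per-age
ingestion and body-weight survey data behind a published table are not
available.

## The synthetic-data generator

The concentration datasets and the exposure table the pipeline consumes
come from national surveys and laboratory campaigns that are not
redistributable, so `ricerisk` generates statistically matched stand-ins:

* `generate_concentration_data()` draws 64 white (market) samples from a
  zero-truncated Normal(100.17, 44.62) ng/g and 90 brown samples — 69
  farm (split 19 Irga 424 at 80.7 ± 22.35, 48 Puitá at 46.58 ± 31.68, 2
  unclassified at the pooled 57.36 ± 34.36) and 21 market at
  154.91 ± 44.8 — from lognormals moment-matched to each stratum
  (pooled brown concentrations are right-skewed and lognormal-selected).
  Farm samples carry a cadmium value correlated with iAs at a latent
  $r = 0.049$; the Cd marginal (10 ± 5 ng/g) is a fixture constant.
* `generate_exposure_table()` builds 27 age bins — "<1" with
  $ED = 8/12$ y (solid food from 4 months), yearly bins 1–19, then 5- and
  10-year bins to 70; $\sum ED = 69.67$ y. Body weight follows a
  piecewise-linear growth curve through fixture anchors (≈8 kg infancy,
  60 kg adult plateau, mild decline after 65). Ingestion rates pin two
  aggregate constraints exactly: every adult bin at 167 g/day and an
  ED-weighted all-age mean of 156.6 g/day, with a monotone child profile
  scaled to close the balance. The child intake shape and body-weight
  anchors are plausible fixtures, not survey claims.

What passing tests therefore show: the pipeline recovers generator
parameters, satisfies its algebraic identities, and reproduces
table-invariant scenario reductions. What they do not show: agreement
with any particular population's per-age risk levels, which depend on the
real survey microdata; absolute ILCR levels from the synthetic table
should be read as illustrative.

## Numerical and testing choices

Test problem sizes are chosen so the full suite runs in well under a
minute of simulation time: 100,000 iterations where a published figure is
being reproduced or a percentile checked, 20,000–50,000 for oracle and
invariance properties (bounds are stated in Monte Carlo standard errors,
so they are size-free), 200 seeded replicates for selection-frequency and
power properties, n = 5,000 for parameter recovery. Degenerate inputs are
defined, not errors: a zero-sd normal is a point mass (simulation then
reproduces the closed form exactly and all percentiles equal the mean);
an empty term table sums to zero risk; a single-value group reports an
undefined sd.

## Known limitations

* Oral ingestion of raw-rice-equivalent only: no dermal or inhalation
  routes, no cooking/washing losses, no bioavailability adjustment, no
  rice-derived products.
* Exposure factors are fixed constants per age bin; the simulation
  propagates concentration uncertainty only (no 2-D
  variability-uncertainty separation, no correlated exposure factors).
* ILCR is total-cancer potency-based; no site-specific partitioning.
* No censored-data likelihood for non-detects and no goodness-of-fit
  testing beyond AIC ranking.
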