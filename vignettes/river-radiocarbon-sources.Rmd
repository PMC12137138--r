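---
title: "Partitioning river CO2 emissions by radiocarbon: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Partitioning river CO2 emissions by radiocarbon: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riverc14)
```

## The problem

River networks outgas on the order of 2 Pg C yr⁻¹ of CO₂. Whether that
carbon cycled through the biosphere in the last decades or sat in soils
and rocks for millennia changes what the flux means for the contemporary
carbon budget. Radiocarbon separates the candidates: carbon fixed since
the 1955 bomb spike carries F¹⁴C > 1, aged soil carbon sits below 1, and
petrogenic (rock-derived) carbon contains no ¹⁴C at all. `riverc14` turns
a heterogeneous collection of river ¹⁴C measurements into a global
source apportionment, with every processing rule explicit and tested.

## Isotope arithmetic

Two constants coexist and must not be mixed. The decay correction between
collection year and 1950 in the F¹⁴C/Δ¹⁴C inter-conversion uses the true
decay constant λ = 1/8267 yr⁻¹:

$$\Delta^{14}\mathrm{C} = 1000\,(F^{14}\mathrm{C}\,e^{-\lambda(y-1950)} - 1)$$

Conventional radiocarbon ages, by long-standing convention, use the Libby
mean life of 8033 yr: age = −8033 ln F¹⁴C. The package pins this choice
with a regression test: the Libby constant reproduces all of the
fraction-modern/age pairs the analysis reports (0.914 → 722 yr,
0.961 → 320 yr, 0.879 → 1036 yr, and the 0.02 offset at F¹⁴C ≈ 1 → 162 yr)
to the nearest year, while 8267 reproduces none of them. Samples with
F¹⁴C > 1 are flagged "modern" and get no age — never a negative one.
Uncertainty on a derived age uses first-order propagation,
σ_age = 8033 σ_F / F.

## Atmospheric normalization

`normalize_f14c()` divides each sample by the annual atmospheric ¹⁴CO₂
value of its collection year (F¹⁴C_atm = Fm_sample / Fm_atm). The package
treats the atmospheric record as a single global annual series; hemisphere
splitting and sub-annual variation are out of scope, and a record supplied
at finer resolution is averaged to annual means on read. Years outside the
record raise an error — silent clamping would quietly reuse the wrong
atmosphere.

Records ending in 2019 are extended to later years by an ordinary
least-squares line through the six annual values 2014–2019, the window in
which the post-bomb decline had flattened to near-linearity. OLS on annual
means is the minimal reading of "extrapolating the declining trend"; the
fitted slope and intercept are attached to the extended record so the
choice is auditable. The extension is idempotent and never alters measured
years.

## Database harmonization

`ingest_observations()` validates every row (compound ∈ {DIC, CO₂, CH₄},
year ≥ 1950, coordinates and flags in range, F¹⁴C > 0) and back-fills
whichever of F¹⁴C/Δ¹⁴C is missing from the other. Rows that fail are
dropped *and logged with a reason*; a conservation identity (kept +
dropped = input, and after collapsing, + removed-by-collapse) is part of
the metadata and of the test suite.

Site-years sampled more than four times for one compound are collapsed to
their arithmetic mean. Two decisions here were genuinely open:

* **Grouping.** The more-than-four rule is applied per compound, because
  DIC, CO₂ and CH₄ are analysed separately everywhere downstream.
* **Collapsed uncertainty.** The averaging convention cited in the
  literature is not spelled out, so the package uses a conservative,
  documented rule: the larger of the replicate standard error
  (sd/√n) and the quadrature-propagated mean of the replicate analytical
  sigmas (√Σσ²/n).

Catchment areas are classified twice: a binary split at 10 km² (the lower
basin-size limit of HydroATLAS) and decade bins labelled by their upper
bound, left-open and right-closed so every positive area lands in exactly
one bin (10 km² is "small"; 10.1 km² is not). The lithology and biome
simplifications are fixed total maps from the HydroATLAS code lists to
three and eight classes respectively; unknown codes are excluded (with a
warning), and ice/glacier reaches — in practice the Antarctic samples —
are excluded from lithology summaries only, not from the database.

## The petrogenic-constrained Monte Carlo

The global mass balance fixes the total DIC flux
T = lateral export (0.52 ± 0.17) + vertical emission (2.0 ± 0.2)
(+ carbonate precipitation, 0 at the global scale) = 2.5 Pg C yr⁻¹. The
package reports the quadrature uncertainty √(0.17² + 0.2²) ≈ 0.26.

Each of the 10,000 runs draws three quantities independently:

| quantity | default law | window |
|---|---|---|
| petrogenic flux P | uniform | 0.150–0.218 Pg C yr⁻¹ |
| F¹⁴C_decadal | uniform | 1.011–1.442 |
| F¹⁴C_millennial | uniform | 0.808–0.874 |

and then computes, with F¹⁴C_petro = 0,

1. residual F¹⁴C = F¹⁴C_river · T / (T − P);
2. raw split a_raw = (residual − F_mil)/(F_dec − F_mil), b_raw = 1 − a_raw;
3. petrogenic share c = P/T, final a = a_raw(1 − c), b = b_raw(1 − c),
   so a + b + c = 1 to machine precision per run.

Design choices, each surfaced in the interface:

* **Uniform draws.** The source windows are stated as ranges (mean ± 1σ to
  printed rounding) without a named law; uniform over the window is the
  assumption-minimal choice and reproduces the reported means and sigmas.
  A truncated-normal alternative sits behind `distribution = "truncnorm"`.
* **Independence.** No correlation structure among the three draws is
  specified, so none is imposed.
* **No clamping.** Raw proportions outside [0, 1] (impossible with the
  default non-overlapping windows, possible with user-supplied ones) are
  flagged, never truncated — truncation would bias the summary means.
* **Fixed total.** T is held at its mean during the simulation; only the
  three listed quantities vary. The vertical-emission uncertainty enters
  later, in `partition_to_fluxes()`, which reports both the combined sigma
  and the proportion-only sigma so the two conventions can be compared.
* **Default bulk signal.** `f14c_river = 0.919`, the mean across DIC, CO₂
  and CH₄ in the assembled database; any observation set run through the
  pipeline overrides it.
* **Seed.** Default 20250604; results carry the seed and are bit-identical
  under it.

`residence_time_range()` converts a carbon stock and a loss flux to a
steady-state turnover bracket, pairing the pessimistic sigma bounds
((stock − σ)/(flux + σ) to (stock + σ)/(flux − σ)) and rounding display
values to the nearest century.

## The Bayesian cross-check

The Monte Carlo leans on a flux prior for the petrogenic share. The
Bayesian model deliberately does not: proportions (a, b, c) get a flat
Dirichlet(1, 1, 1) prior on the simplex, the endmember values get normal
priors truncated to their stated windows, and the single likelihood term
is F¹⁴C_river ~ Normal(aF_dec + bF_mil, σ). The default σ = 0.03 is the
order of the millennial endmember sigma; supply the standard error of an
observation-set mean when one is available.

The sampler is random-walk Metropolis, but parameterized for the
geometry of this posterior: the chain moves in (μ, c) coordinates, where
μ = aF_dec + bF_mil is the direction the likelihood constrains and c
indexes the ridge of simplex points sharing that μ. Given the endmembers
the map to (a, b, c) is linear, so the flat prior stays flat, and the two
coordinates are nearly independent a posteriori — the regime in which
componentwise random walk with step adaptation (every 50 warm-up
iterations, toward 35 % acceptance) mixes well even for very small σ. A
prior-independence move is mixed in each iteration: a fresh Dirichlet draw
whose proposal density cancels the prior exactly, leaving a pure
likelihood-ratio acceptance. This kernel makes the prior-predictive check
(likelihood off ⇒ posterior = prior, verified on the Dirichlet moments)
essentially i.i.d. and gives the chain global jumps when the likelihood is
narrow. Four chains by default; the fit *fails* (rather than warns) if any
parameter's potential scale reduction exceeds 1.05, with effective sample
sizes reported per parameter via `coda`.

`compare_mc_bayes()` reports per-source mean differences and ±1σ interval
overlap. On the defaults the two apportionments agree within 0.15 per
source — the level of agreement the analysis claims, checked in the
acceptance suite, not assumed.

## What the synthetic generator emulates — and what it does not

`make_atmospheric_record()` is a parametric bomb curve: plateau at 0.975,
logistic rise to 1.85 in 1964, exponential relaxation (e-folding 16 yr)
toward 1.0. Those values are emulation choices that give the curve the
right shape and dynamic range; they are not a fit to the published
compilation, and nothing in the acceptance surface depends on them — the
printed-constant targets use printed constants only.

`simulate_observations()` builds each observation as
a·F_dec + b·F_mil + c·0 + lithology offset + Normal(0, σ_meas) truncated
positive, with per-observation proportions from a Dirichlet around a
configurable mean (defaults 0.43/0.50/0.07, precision 50), a gamma decadal
lag (mean 10 yr, shape 4 — recent photosynthate is not instantaneous), a
log-normal millennial age (median 1500 yr, σ_log 0.5, spanning the
centuries-to-millennia soil pool), analytical σ_meas = 0.02 (a typical
reported AMS-era uncertainty for these compilations), a compound mix of
85/10/5 % DIC/CO₂/CH₄ mirroring the database's DIC dominance, and
lithology offsets (−0.02/0/+0.02 for sedimentary/igneous/metamorphic)
that qualitatively mirror the observed ordering. Five percent of
observations arrive as six-replicate site-years so the collapsing rule is
exercised end to end. The millennial component uses the true decay
constant (exp(−age/8267)); the Libby constant is only ever a reporting
convention.

Not emulated: spatial autocorrelation, seasonality, per-study reporting
quirks, gas-transfer physics, and any coupling between covariates and the
mixture proportions beyond the additive lithology offset. Passing
recovery tests therefore show the *pipeline* is unbiased under its own
assumptions — they cannot show the assumptions hold for real rivers.

`recovery_experiment()` closes the loop: simulate → harmonize → collapse →
mean F¹⁴C → Monte Carlo partition with endmembers matched to the
generator's brute-force expectations and the petrogenic window centred on
the true share. The test suite requires per-source |bias| < 0.05 at 1000
observations × 20 replicates, and near-exactness (< 0.01) when noise is
off and the windows are tight.

## Numerical choices and degenerate inputs

* Conversion round trips hold to 1e-12 across F¹⁴C ∈ [0.01, 2],
  years 1950–2030; a year outside that window warns but converts.
* Δ¹⁴C ≤ −1000 ‰, F¹⁴C ≤ 0, non-positive areas, petrogenic flux ≥ total,
  equal endmembers, and flux σ ≥ flux mean all raise typed errors rather
  than returning NaN.
* Group summaries with n = 1 report sd = 0 with an explicit `n1_flag`
  instead of NA, so downstream tabulation never silently drops groups.
* All stochastic entry points take a seed, restore the caller's RNG state
  on exit, and are bit-reproducible.

Problem sizes in the shipped tests — 10,000 Monte Carlo runs, 20 × 1000
observations for recovery, a dozen reduced-length chains for the
credible-interval calibration check — were chosen as the smallest sizes at
which the statistical assertions are stable across seeds.

## Known limitations

* The global partition uses one bulk F¹⁴C_river; catchment-specific
  weathering inversions would need solute data the assembled literature
  rarely reports.
* The Bayesian petrogenic endmember is fixed at exactly 0; a narrow prior
  around 0 would loosen the posterior petrogenic share.
* DIC is taken as a surrogate for emitted CO₂ on the strength of the
  paired-sample offset check (`paired_offset()`, typically ≤ 0.02 F¹⁴C
  units, ≈ 162 ¹⁴C yr at F¹⁴C ≈ 1); where equilibration with the
  atmosphere is substantial the old-carbon shares are conservative.
* Calendar-year calibration (IntCal), reservoir corrections and δ¹³C
  fractionation corrections are out of scope; inputs are assumed already
  corrected by the reporting laboratories.
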