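# riverc14

Radiocarbon source apportionment of river carbon emissions.

Rivers emit roughly 2 Pg C yr⁻¹ of CO₂ to the atmosphere. How much of that
carbon was fixed by photosynthesis in the last few decades, how much is
aged soil organic matter, and how much is ¹⁴C-dead rock ("petrogenic")
carbon mobilized by weathering? The radiocarbon content of river dissolved
inorganic carbon (DIC), CO₂ and CH₄ — reported as fraction modern, F¹⁴C —
carries that fingerprint, but using it at the global scale requires a chain
of careful steps: unit conversions, normalization to the atmospheric bomb
curve, harmonization of heterogeneous literature data, and an isotope
mass-balance mixing model with honest uncertainty propagation. `riverc14`
implements that chain as a tested R package, for biogeochemists working
with river (or other aquatic) ¹⁴C data.

## The model

**Conversions.** Fraction modern, Δ¹⁴C and conventional age are linked by

- Δ¹⁴C = 1000 · (F¹⁴C · e^(−λ(y−1950)) − 1), with λ = 1/8267 yr⁻¹ and *y*
  the collection year;
- conventional age = −8033 · ln(F¹⁴C) (Libby mean life; undefined —
  "modern" — when F¹⁴C > 1).

**Normalization.** F¹⁴C_atm = Fm_sample / Fm_atmosphere(y) divides each
sample by the atmospheric ¹⁴CO₂ of its collection year, removing the
imprint of the post-1955 bomb spike so samples from different decades are
comparable.

**Mass balance.** Global river DIC export is partitioned as

    total DIC flux = lateral export to ocean + vertical CO₂ emission
                     (+ carbonate precipitation)

and its isotopic composition as a three-source mixture

    F¹⁴C_river = a · F¹⁴C_decadal + b · F¹⁴C_millennial + c · F¹⁴C_petro,
    a + b + c = 1.

With the petrogenic endmember at F¹⁴C = 0 and published bounds on the
petrogenic weathering flux, the non-petrogenic residual
F¹⁴C = F¹⁴C_river · T / (T − P) is split between the decadal and millennial
endmembers; a Monte Carlo simulation over the petrogenic-flux and
endmember ranges propagates the uncertainty. An independent Bayesian
three-endmember model (flat Dirichlet prior on the simplex, Gaussian
likelihood, endmember uncertainty marginalized; no flux prior at all)
cross-checks the result.

A synthetic-data generator with recorded ground truth closes the loop:
it emulates the bomb curve and builds observation databases from known
mixtures, so the whole pipeline's ability to recover generating source
proportions is itself under test.

## Worked example

```r
library(riverc14)

# one measurement: Amazon mainstem DIC, 2005
radiocarbon_value(0.914, 0.004, 2005)
#> F14C 0.9140 +/- 0.0040 (2005 CE): Delta14C -92.1 permil, age 722 14C yr BP

# global source partition at the database mean F14C of 0.919
mc <- monte_carlo_partition(flux_budget(), endmember_set(),
                            f14c_river = 0.919, n_runs = 10000,
                            seed = 20250604)
mc
#> Monte Carlo source partition (n = 10000, seed = 20250604, F14C_river = 0.919)
#>   decadal    0.41 +/- 0.16
#>   millennial 0.52 +/- 0.16
#>   petrogenic 0.07 +/- 0.01
#>   old carbon 0.59 +/- 0.16

partition_to_fluxes(mc)
#>       source      mean         sd sd_proportion_only
#> 1    decadal 0.8150982 0.32827174         0.31559133
#> 2 millennial 1.0390208 0.33507976         0.31791509
#> 3 petrogenic 0.1461307 0.02128007         0.01559791
#> 4        old 1.1851514 0.33744296         0.31559133
```

Read: at the database-mean river signal, about 41 % of river CO₂ emission
is decadal carbon, 52 % millennial and 7 % petrogenic, i.e. ~59 % ("old
carbon", millennial + petrogenic) of the 2.0 Pg C yr⁻¹ vertical flux —
about 1.2 Pg C yr⁻¹ — left the active carbon cycle centuries to millennia
ago. Feeding the millennial flux back into a soil-stock turnover
calculation:

```r
rt <- residence_time_range(840, 280, 1.1, 0.3)
#> soil residence time: 400-1400 yr
```

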