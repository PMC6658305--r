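# feverpattern

Postvaccination fever episode extraction and pattern analysis from
caregiver-recorded temperatures.

## What this is for

After a childhood vaccination, caregivers using fever-management apps
record body temperatures at irregular, self-chosen times, along with any
antipyretic doses given. Buried in those logs is the natural course of
postvaccination fever — when it starts, how high it gets, how long it
lasts, and how antipyretics bend the curve. `feverpattern` is an R
package for epidemiologists and biostatisticians working with such
patient-generated health data (PGHD). It provides:

* **Episode extraction.** Readings are interpolated piecewise-linearly;
  with fever threshold θ = 38.0 °C, *onset* is the first time the imputed
  curve reaches θ (exact segment inversion; censored if the first reading
  is already febrile), *offset* the last time it falls below θ,
  *duration* = offset − onset, and *Tmax* the maximum raw reading within
  48 h of vaccination.
* **A record-selection cascade**: complete demographics → single
  vaccinations only → ≥ 5 in-window readings → episode with both onset
  and offset → vaccines with ≥ 100 surviving records, with per-stage
  survivor counts.
* **Antipyretic pattern analyses**: hourly timing of the first dose and
  the distribution of temperature at dosing in 0.1 °C bins.
* **The inferential battery** used in this setting: Welch two-sample
  tests; one-way ANOVA with a mean-centred Levene check; Dunnett T3
  all-pairs post hoc comparisons via the studentized maximum modulus
  distribution (authored here, with both quadrature CDF `psmm()` and a
  Monte Carlo sampler `rsmm()`); logistic regression for high fever
  (Tmax ≥ 39.0 °C) on age, weight and sex with Wald odds ratios and
  variance-inflation-factor screening.
* **Onset-aligned trajectories**: mean temperature in 1-h bins over
  [−3, +24] h around onset with 95% bands, plus straight-line decay fits.
* **A seeded synthetic cohort simulator** (vaccine-specific triangular
  fever pulses, caregiver-driven measurement intensity, threshold-
  triggered dosing with a 4.4 h linear suppression) so the entire
  pipeline is testable by parameter recovery without proprietary data.

## Worked example

Extract an episode from three readings — 37.0 °C at vaccination, 39.0 °C
at 6 h, 37.0 °C at 12 h. The curve crosses 38.0 °C halfway up and halfway
down:

```r
library(feverpattern)
extract_episode(c(0, 6, 12), c(37.0, 39.0, 37.0))
#>   onset_h offset_h duration_h tmax_c onset_censored
#> 1       3        9          6     39          FALSE
```

Simulate a cohort, apply the cascade, and look at dosing behaviour:

```r
co <- simulate_cohort(800, seed = 1)
fr <- apply_cascade(co$readings, co$events, co$doses,
                    fever_config(min_records_per_vaccine = 20))
fr
#> Analyzable postvaccination records
#>   entered                             800
#>   with demographics                   800
#>   single vaccination                  800
#>   ≥ 5 readings in window              769
#>   episode with onset and offset       597
#>   vaccine with ≥ 20 records           597
#>   antipyretic records: 473 (79.2%)

first_dose_timing(fr)
#> First antipyretic dose timing (n = 473)
#>   within  1 h:  0.63%
#>   within 10 h: 57.29%
#>   within 24 h: 94.29%

temperature_at_dose(fr)
#> Temperature at first antipyretic dose (473 located, 0 unlocatable)
#>   at or above fever threshold: 89.85%
#>   below 37 °C: 5.92%   above 40 °C: 0.00%
```

About 90% of first doses fall at a measured temperature of 38.0 °C or
above — caregivers treat the threshold as a trigger — and more than half
of first doses arrive within 10 h of vaccination, tracking fever onset.

With 400 records per vaccine, the Dunnett T3 partition of extracted Tmax
recovers the programmed three-tier severity ordering:

```r
kin <- default_kinetics()
co <- simulate_cohort(2000, seed = 1, vaccine = rep(kin$vaccine, each = 400))
fr <- apply_cascade(co$readings, co$events, co$doses)
dunnett_t3(fr$episodes$tmax_c, fr$episodes$vaccine)$partition
#> [[1]]
#> [1] "hepatitis A" "influenza"
#> [[2]]
#> [1] "Japanese encephalitis" "DTaP"
#> [[3]]
#> [1] "pneumococcus"
```

`run_fever_pipeline(out_dir, n_children = 3000, seed = 1)` runs the whole
chain and writes `episodes.csv`, `cascade.json`, dosing and trajectory
JSON, a Markdown report, and a manifest with input digests; runs are
byte-identical for a fixed seed.

See `vignettes/postvaccination-fever.Rmd` for the model details, the
generator's assumptions, and what the tests do and do not establish.

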