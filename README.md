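# tremorkit

Quantitative analysis of parkinsonian tremor from upper-limb inertial
measurement unit (IMU) recordings.

Clinicians grade tremor by eye on ordinal scales (UPDRS item 21: 0–4 per
hand). Wireless IMUs strapped to the upper arm, forearm and hand record
tri-axial acceleration and angular velocity during standardised motor
tasks — the finger-to-nose test (kinetic tremor) and holding an
outstretched arm (postural tremor) — and allow that grading to be put on a
quantitative footing. `tremorkit` implements the full analysis chain for
such recordings, for movement-disorder researchers and engineers working
with wearable-sensor data:

* **Preprocessing** — first-order Butterworth high-pass (1 Hz cut-off,
  causal, prewarped bilinear design) plus gravity/DC removal on the
  acceleration channels, with a 2 s start-up transient excluded.
* **Spectral features** — one-sided rectangular-window periodogram
  `P(f) = |Σ x(n) e^{-i2πfn/Fs}|² / (L·Fs)` and the dominant tremor
  frequency `f`, taken across axes from the axis with the highest peak
  power.
* **Nonlinear and intensity features** — approximate entropy
  `ApEn = Φ^m(r) − Φ^{m+1}(r)` with `m = 2`, `r = 0.45·SD` (standard
  Pincus formulation, C++ kernel, brute-force-oracle-verified) and root
  mean square, both computed on the resultant magnitude
  `√(x² + y² + z²)`.
* **Trial aggregation** — three trials per task averaged into a
  per-(subject, side, segment) table of the twelve metrics
  (`f`, `rms`, `apen` × kinetic/postural × acc/gyr).
* **Group statistics** — per-metric, per-segment one-way ANOVA
  (patients vs controls at α = 0.05, and UPDRS 0-vs-1 sides within
  patients), with publication-style `mean ± SD` rendering.
* **Synthetic cohorts** — a fully seeded generator (tremor oscillation
  with frequency jitter and amplitude modulation, sub-1-Hz voluntary
  movement, gravity, white noise) so the entire pipeline is testable
  without clinical data.

Everything is tidyverse-native: recordings and feature tables are tibbles,
results chain with the pipe, fitted comparisons have `tidy()`/`glance()`
methods and `autoplot()` diagnostics.

## Worked example

```r
library(tremorkit)
library(dplyr)

cohort <- simulate_cohort(cohort_spec(n_pd = 4, n_co = 4, duration = 10,
                                      master_seed = 42))
cohort
#> <imu_cohort: 288 recordings, 8 subjects (4 PD / 4 CO), fs = 51.2 Hz>

features <- cohort$trials |>
  mutate(recording = purrr::map(recording, preprocess_recording)) |>
  extract_features()

features |>
  select(subject_id, group, side, segment,
         f_kin_acc, rms_kin_gyr, apen_kin_acc) |>
  head(4)
#> # A tibble: 4 × 7
#>   subject_id group side  segment   f_kin_acc rms_kin_gyr apen_kin_acc
#>   <chr>      <chr> <chr> <chr>         <dbl>       <dbl>        <dbl>
#> 1 CO01       CO    left  forearm        4.08        11.2        0.352
#> 2 CO01       CO    left  hand           4.12        11.4        0.386
#> 3 CO01       CO    left  upper_arm     4.16        10.7        0.343
#> 4 CO01       CO    right forearm        4.12        10.8        0.423

cmp <- compare_pd_vs_co(features)
glance(cmp)
#> # A tibble: 1 × 5
#>   groups   n_tests n_significant prop_significant alpha
#>   <chr>      <int>         <int>            <dbl> <dbl>
#> 1 CO vs PD      72            47            0.653  0.05

render_summary_tables(cmp) |>
  filter(metric == "apen_kin_acc", side == "right") |> head(3)
#> # A tibble: 3 × 8
#>   metric       side  segment   CO                  PD            F       p sig
#> 1 apen_kin_acc right forearm   0.400 ± 0.018 (n=4) 0.992 ± …  499. 5.25e-7 *
#> 2 apen_kin_acc right hand      0.441 ± 0.024 (n=4) 0.959 ± … 1277. 3.20e-8 *
#> 3 apen_kin_acc right upper_arm 0.376 ± 0.012 (n=4) 1.038 ± …  295. 2.5 e-6 *
```

Each row reads as in a cohort table: control and patient group
`mean ± SD` for one metric on one segment, the ANOVA F statistic and
p-value, and a `*` marking significance at α = 0.05. Here the simulated
patients' kinetic-task acceleration signals are markedly more irregular
(ApEn ≈ 1.0 vs ≈ 0.4), as the generator's presets encode. The dominant
frequencies near 4 Hz recover each simulated subject's drawn tremor
frequency; `rms_kin_gyr` is the angular-velocity tremor intensity in °/s.

`run_pipeline(run_config(...))` wraps the same chain end to end (simulate
or ingest a directory of recording CSVs, write feature tables, comparison
tables, a run log and a manifest), and `inst/exec/tremorkit` exposes it as
a command line (`simulate`, `analyze`, `fixture` subcommands).

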