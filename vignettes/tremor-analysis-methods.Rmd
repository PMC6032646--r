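---
title: "Quantifying parkinsonian tremor from IMU recordings: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying parkinsonian tremor from IMU recordings: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tremorkit)
library(dplyr)
```

## The measurement problem

Tremor — rhythmic involuntary oscillation of a body part — is a cardinal
motor sign of Parkinson's disease (PD). In the clinic it is graded by eye on
ordinal scales (UPDRS item 21 scores hand action/postural tremor 0–4 per
side), which is fast but coarse and rater-dependent. Wearable inertial
measurement units (IMUs) offer an objective alternative: small wireless
sensors on the upper arm, forearm and hand record tri-axial linear
acceleration and angular velocity while the subject performs standardised
tasks — the finger-to-nose test (kinetic tremor) and holding the arm
outstretched (postural tremor).

tremorkit implements the full quantitative chain for such recordings:

1. **Preprocessing** — 1 Hz first-order Butterworth high-pass and gravity
   removal.
2. **Feature extraction** — three scalar metrics per signal (acceleration /
   angular velocity) and task:
   * dominant frequency $f$ from the rectangular-window periodogram, with a
     cross-axis rule;
   * root mean square (RMS), the intensity of the oscillation;
   * approximate entropy (ApEn), the irregularity of the series.
3. **Group statistics** — per-metric, per-segment one-way ANOVA comparing
   patients with controls, and score-0 vs score-1 sides within patients.

Because clinical recordings of this kind are rarely shareable, the package
also ships a seeded synthetic-cohort generator with the statistical
structure the analysis assumes, so every stage is testable end to end.

## Signal model and preprocessing

Raw accelerometer channels contain the gravity projection (a quasi-static
offset of up to 9.81 m/s²), slow voluntary movement (the finger-to-nose
cycle is well below 1 Hz), the tremor oscillation of interest (roughly
1–10 Hz), and broadband sensor/motor noise. The preprocessing removes the
first two: each acceleration channel has its mean subtracted and every
channel is passed through a first-order digital Butterworth high-pass with
1 Hz cut-off, designed by bilinear transform with frequency prewarping so
that $|H(1\,\mathrm{Hz})| = 1/\sqrt{2}$ exactly and $|H(0)| = 0$ exactly.

Design choices worth making explicit:

* **Causal, forward-only filtering.** A forward–backward pass would square
  the magnitude response and double the effective order; phase distortion
  is irrelevant here because every downstream metric (peak frequency, RMS,
  ApEn) is insensitive to phase. The filter state is initialised to the
  steady state for a constant input equal to the first sample, which
  suppresses the start-up spike that a zero state would produce on signals
  with a DC offset.
* **Transient exclusion.** The first 2 s of every filtered recording are
  flagged and excluded from all features. The filter time constant is only
  ≈ 0.16 s, so 2 s is deliberately conservative.
* **Gyroscope channels are filtered too.** Angular-velocity channels have
  no gravity component, but slow voluntary rotation contaminates them the
  same way; the same high-pass is applied to all six channels.
* **Residual means.** After high-passing, the window mean of a
  deterministic offset-plus-oscillation signal is negligible (tested at
  $10^{-3}$ of the RMS). For stochastic 28 s windows, finite-window
  spectral leakage of 0.4–5 Hz content bounds the achievable residual mean
  near the percent level; that is a property of finite windows, not of the
  filter.

## Spectral estimate and dominant frequency

The power spectral density is the one-sided rectangular-window periodogram

$$P(f_k) = \frac{1}{L F_s}\left|\sum_{n=0}^{L-1} x(n)\,
e^{-i 2\pi f_k n / F_s}\right|^2,$$

computed on the post-transient window with no zero-padding, tapering,
detrending or segment averaging; interior bins are doubled so that
$\sum_k P(f_k)\,\Delta f$ equals the mean square of the input (Parseval).
The frequency resolution is $F_s/L$ — 0.036 Hz for a 28 s window at
51.2 Hz.

The dominant frequency of a tri-axial signal uses a cross-axis rule: each
axis contributes the frequency of its largest in-band periodogram peak, and
the axis with the largest peak power wins. Ties are broken towards the
lower frequency, then the lower axis index — documented, deterministic, and
exercised in the tests. The default search band is 1 Hz (the high-pass
cut-off) to the Nyquist frequency; it can be narrowed (e.g. to 1–10 Hz) to
exclude high-frequency artefacts.

## Approximate entropy

ApEn quantifies the unpredictability of a series: for embedding length
$m$ and tolerance $r$, $\Phi^m(r)$ is the average log-fraction of
length-$m$ templates that stay within Chebyshev distance $r$ of each
other (self-matches included, $\le$ comparison), and

$$\mathrm{ApEn} = \Phi^m(r) - \Phi^{m+1}(r).$$

The package uses the standard Pincus formulation — a difference of
averaged log-counts — rather than a log of a ratio of aggregate counts
that sometimes appears in condensed notation; the two differ only through
the averaging order, and the standard form is the one to which the usual
parameter recommendations apply. Parameters follow those
recommendations: $m = 2$ and $r = 0.45\,\sigma$, where $\sigma$ is the
population standard deviation (divisor $N$) of the analysed post-transient
series; the difference from the sample SD is $O(1/N)$ and a convention had
to be pinned. The $O(N^2)$ template counting is implemented in C++ with an
early-exit inner loop; a deliberately naive double-loop R implementation
serves as the oracle in the test suite and the two agree to $10^{-12}$.

RMS and ApEn are computed on the **resultant magnitude**
$\sqrt{x^2+y^2+z^2}$ of the preprocessed signal rather than per axis: the
reported quantity is a single scalar per segment and signal, and the
magnitude is invariant to sensor orientation. A per-axis mode (using the
axis selected by the dominant-frequency rule) is available behind the
`per_axis` switch for sensitivity analysis.

Each subject performs each task three times; per-subject features are the
arithmetic mean over available trials (the aggregation is not prescribed
anywhere authoritative, so the package states its choice and also retains
the trial-level table).

## Group statistics

For every combination of the twelve metrics, two sides and three segments
(72 tests with the full design), a classical fixed-effects one-way ANOVA
compares PD against CO at $\alpha = 0.05$; within the PD group, sides
scored 0 and 1 on UPDRS item 21 are compared per side. Sides are analysed
separately. Deliberately, **no multiple-testing correction** drives the
significance flags — the reference analysis reports raw per-test
significance — but a Benjamini–Hochberg-adjusted column (`p_bh`) is
emitted alongside, clearly marked as an extension. Group SDs are reported
with divisor $n-1$, the convention for cohort tables. Scores above 1 are
excluded from the stratified comparison with a warning. ANOVA
distributional assumptions are not checked, matching the reference
procedure; the tests verify instead that the two-group ANOVA equals the
squared pooled-variance t statistic and that the whole simulate→ANOVA
chain holds its nominal type-I error.

## The synthetic cohort

Each simulated trial is

$$\mathbf{a}(t) = \mathbf{g} + A(t)\sin\!\big(\phi(t) + \varphi_i\big)\,
a_i\,\hat{\mathbf{u}} + V \sin(2\pi f_v t)\,\hat{\mathbf{v}} +
\boldsymbol\varepsilon(t),$$

with $\phi(t)$ integrating an instantaneous frequency that performs a
bounded random walk (reflected at ±1.5 Hz around the centre frequency),
$A(t)$ a smooth envelope $1 + c\,\xi(t)$ floored at zero ($\xi$ is
unit-SD noise smoothed over ≈ 1 s), a constant gravity vector on
acceleration channels only, a sub-1-Hz voluntary component present in the
kinetic task only, and white Gaussian noise. Direction cosines and phases
are drawn once per trial. Angular-velocity channels are built the same way
without gravity; the voluntary term has its own angular-velocity amplitude
(`voluntary_amp_gyr`), since a slow reaching movement rotates the limb as
well as translating it.

Seeding is hierarchical and purely deterministic: the master seed derives
one seed per (subject, side) for the parameter draws and one per trial for
the signal realisation, via a Lehmer step with a stream index. Parameter
draws do not depend on which tasks, segments or sides are simulated, so a
subset cohort shares its ground truth with the full factorial — convenient
for focused simulation studies.

### What the group presets encode — and why

The shipped presets were calibrated once, at design time, by simulation:

|                       | PD preset | CO preset |
|-----------------------|-----------|-----------|
| tremor centre freq    | 5 Hz      | 5.5 Hz    |
| tremor amp (acc)      | 1.0 m/s²  | 0.15 m/s² |
| tremor amp (gyr)      | 30 °/s    | 4 °/s     |
| freq jitter SD        | 0.6 Hz/√s | 0.15      |
| amp modulation SD     | 0.35      | 0.10      |
| noise SD (acc, gyr)   | 0.12, 2.5 | 0.04, 0.8 |

Both groups share the voluntary finger-to-nose component (0.4 Hz, 2 m/s²,
40 °/s). Exploratory simulation showed that on the resultant-magnitude
series, ApEn is governed mainly by the *composition* of the signal — how
much fast, broadband content it carries relative to its total SD — and
only weakly by slow frequency jitter or amplitude modulation. Making the
groups differ solely in jitter/modulation therefore cannot reproduce the
clinically observed contrast (patients more irregular); worse, a
higher-frequency low-amplitude control tremor *inflates* control ApEn.
The presets instead encode the clinically sensible picture: control
recordings are dominated by the smooth voluntary movement plus a small
fast tremor (regular → low ApEn, low RMS), while patient recordings carry
a strong, jittery, noisier tremor (irregular → high ApEn, high RMS).
Patients still have strictly larger jitter and modulation, and tremor
amplitude attenuates towards the shoulder (hand 1.0, forearm 0.7, upper
arm 0.45), matching the distal predominance of parkinsonian tremor.

The clinical score is assigned per side by thresholding the drawn
angular-velocity tremor amplitude at 36 °/s, which with the PD
between-subject spread (25 % relative SD) scores roughly a fifth of
patient sides as 1 — the same shape as the 14-vs-4 stratification typical
of a moderate cohort. Default cohort sizes are 19 PD and 12 CO; default
trial duration is 30 s, which at 51.2 Hz gives 1536 samples — 0.033 Hz
spectral resolution and a stable ApEn estimate. (Trial duration is not
prescribed by the reference protocol; 30 s is this package's documented
choice, and the miniature `"smoke"` preset uses 10 s.)

### What the generator does *not* model

No biomechanical limb kinematics, no rest tremor, no slow orientation
drift of the gravity vector (the high-pass removes sub-1-Hz content either
way), no harmonics of the tremor oscillation, and no heavy-tailed or
autocorrelated sensor noise. Consequently, passing tests demonstrate that
the *pipeline* measures what it claims on signals with the assumed
structure — they do not validate clinical discrimination on real
recordings.

## Numerical choices and degenerate inputs

* Sampling uniformity is enforced to $10^{-6}$ relative; the observed time
  grid overrides a disagreeing declared rate (> 0.1 %) with a warning.
* Acceleration is held internally in m/s²; files declaring `units_acc=g`
  are converted by 9.80665 on read.
* Recordings must be ≥ 2 s (and ≥ 2× the transient window for
  preprocessing); ApEn requires $N \ge 50$ and a non-constant series;
  the periodogram requires $L \ge 8$; tremor frequencies at or above
  Nyquist are refused at simulation time.
* A constant series, an empty group, identical values across ANOVA groups,
  or an all-zero spectrum in the search band raise typed conditions
  (`tremorkit_*_error`) rather than propagating NaN.
* Zero within-group variance with distinct means reports $F = \infty$,
  $p = 0$ rather than failing.

## Problem sizes used in the shipped checks

The verification suite runs entirely on synthetic data: oracle equivalence
on 50 series of length ≤ 200; Parseval on 100 random signals; a type-I
calibration over 200 small null cohorts (5+5 subjects, 10 s trials,
kinetic task, right side, forearm+hand); and a power study of the shipped
presets over 100 master seeds of 15+15 subjects (30 s trials, kinetic
task, right side, forearm+hand) plus 30 null seeds at the same size. The
focused factor subsets exploit the seeding scheme above — the drawn
parameters are identical to the full factorial — and keep the whole suite
comfortably reproducible on a laptop.

## Known limitations

ApEn of the magnitude series conflates oscillation frequency with
irregularity (higher-frequency content raises ApEn at fixed sampling
rate); comparisons across groups with very different dominant frequencies
should be interpreted with that in mind. The periodogram has no variance
reduction (no Welch averaging), which is faithful to the reference method
but makes single-trial peak power noisy — the cross-axis rule uses only
the argmax, and trials are averaged at the feature level. The UPDRS
stratification compares scores 0 and 1 only; cohorts whose sides all score
alike cannot be stratified and say so explicitly.
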