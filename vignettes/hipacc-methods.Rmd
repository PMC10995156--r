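---
title: "Processing raw hip-worn accelerometry: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Processing raw hip-worn accelerometry: models, rules and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hipacc)
```

## The problem

Large cohort studies increasingly measure physical activity with raw
triaxial accelerometers worn at the hip for about a week. Before any
epidemiology can happen, the raw signal (sampled at 100 Hz, ±6 or ±8 g,
12-bit) has to pass a quality-control pipeline: sensor-specific offset and
gain drift must be corrected, epochs summarised into interpretable
acceleration metrics, periods when the device was not worn identified and
imputed, days and participants screened against validity rules, and the
surviving data aggregated at several temporal resolutions. `hipacc`
implements that pipeline end to end, together with a synthetic-cohort
generator that provides ground truth for every stage — the study data such
pipelines are built for are typically access-restricted, so all testing
here runs on simulated recordings with known properties.

## Signal metrics

Two epoch summaries are computed per 5-s epoch, both in milli-g
(1 mg ≈ 0.00981 m/s²), with no low-pass filtering (high frequencies carry
harmonics of genuine movement, not just noise):

* **ENMO** (Euclidean norm minus one): mean of
  $\max(\lVert a_i\rVert - 1, 0)$ over the epoch's samples. Truncation is
  applied per sample before averaging, which is the convention of the
  widely used raw-processing toolchain; truncating the epoch mean instead
  is available as `enmo_truncation = "epoch"`. ENMO assumes a
  well-calibrated sensor, since the 1 g subtraction is absolute.
* **MAD** (mean amplitude deviation):
  $\tfrac1n \sum_i\bigl|\lVert a_i\rVert - \overline{\lVert a\rVert}\bigr|$.
  MAD is invariant to a constant shift of the vector norm, hence less
  sensitive to residual calibration error; its values run roughly twice
  ENMO on the same data, so the two metrics' intensity scales are not
  interchangeable.

Posture angles per axis are computed from the per-axis 5-s medians $m$ as
$\arctan(m_i/\sqrt{m_j^2+m_k^2})$, in $[-90°, 90°]$. The median over a 5-s
window is a pragmatic gravity-direction estimator; the exact formula used
by the study toolchain is not published in its main text, so this package
documents its own definition and treats it as part of the method. The
degenerate zero-denominator case maps to ±90° by the sign of $m_i$ (via
`atan2`), and the all-zero vector to 0°.

## Auto-calibration

During non-movement the device measures gravity only, so still-window mean
vectors must lie on the unit sphere; deviations are offset/gain drift. The
fit estimates the per-axis affine correction $a \mapsto g\,a + o$
minimising the distance of still points from the sphere, and the residual
mean $|\,\lVert a\rVert - 1\,|$ is the calibration error. Recordings whose
error stays above **0.02 g** after correction are excluded from analysis.

Three numerical choices matter on hip data, where most still time is spent
in very few postures:

1. **Orientation balancing.** The raw still-point cloud is binned by
   direction (unit vector rounded to a 0.2 grid) and each bin contributes
   one representative: its mean direction rescaled to the members' mean
   norm. Without balancing, a dominant posture with thousands of points
   lets offset and gain trade off against each other while the sphere
   residual stays tiny — the fit is unidentified exactly in the way
   hip-worn wear is prone to. The norm-preserving representative avoids
   chord shrinkage (a plain coordinate mean of points spread over an arc
   sits a few mg inside the sphere).
2. **Weight floor.** Per-point robust weights $1/\max(|r_i|, 10^{-3})$
   concentrate all influence on points accidentally near the sphere when
   the fit is still far away, stalling the iteration. The denominator is
   floored at the mean residual, which makes early iterations effectively
   unweighted and reduces to the robust weights near convergence.
3. **Backtracking.** Each Gauss-Seidel-style update (regress the closest
   sphere point on the raw point, per axis) is accepted at the longest
   step length in $\{1, 1/2, \dots, 1/32\}$ that does not increase the
   residual, so accepted iterations are monotone; iteration stops when no
   damped step improves, parameters move less than $10^{-9}$, or after
   1000 iterations.

A fit is only attempted with at least 72 still points spanning at least
0.3 g on every axis; otherwise the identity correction is returned with a
warning and usability is decided by the uncorrected error. On
orientation-rich synthetic recordings the fit recovers injected offsets
within 5 mg and gains within 0.005 (see `tests/testthat/test-acceptance.R`).

## Non-wear, clipping and imputation

The wear/non-wear decision lives on a grid of 96 15-min slots per day,
aligned to local midnight. For each slot the enclosing **60-min window**
(centered; truncated at recording edges rather than dropped, so the first
and last 22.5 min are still classified) is evaluated per axis: an axis is
*still* if its SD is below **13 mg** *or* its value range below **50 mg**;
the slot is non-wear when at least **2 of 3** axes are still. Both the
OR/AND combination and the axis vote are configurable because the
published rule wording is ambiguous on both counts; the defaults follow
the established procedure's convention. The centered window necessarily
blurs episode edges — the first and last slot or two of a non-wear episode
see a mixed window — which bounds achievable segment accuracy; on labelled
synthetic cohorts the classifier stays above 95%.

Clipping: a sample is "at the edge" when any axis reaches 98% of the
dynamic range (the cutoff is configurable; the source procedure states no
number), a slot is invalid when more than 80% of its samples are at the
edge, and a recording is excluded when more than 30% of its slots are
flagged (again configurable — the study centers' threshold is not public).

Invalid (non-wear or clipped) slots are **imputed** with the mean of the
same clock slot over the days where that slot is valid — not imputing
would count non-wear as zero movement, and dropping the epochs would
implicitly impute with the rest of the recording. A slot invalid on every
recording day cannot be imputed and marks the participant's 24-h cycle
incomplete. Imputed slots never count toward wear time.

## Validity, inclusion and aggregation

A day is valid with at least **16 h** of detected (un-imputed) wear; on
civil-time-shift days the threshold scales with the actual day length
(16/24 × 23 or 25 h), keeping the two-thirds wear fraction constant.
Participants are included with ≥1 valid weekend day, ≥2 valid weekdays and
a complete 24-h cycle; the first failing rule (checked weekend → weekday →
cycle) is the recorded exclusion reason, and a cohort-level flow ledger
telescopes exactly: received = unprocessable + quality-excluded +
validity-excluded + included.

Metrics aggregate at four levels: L1 overall (plain mean over valid days
of daily means — a 5/7–2/7 week reweighting is deliberately *not* the
default), L2 weekday/weekend, L3 per valid day, L4 per 15-min clock slot
across valid days. L1 equals the mean of L3 by construction, and for
complete imputed days the mean of the 96 L4 values reproduces L1 exactly —
both are tested to machine precision.

Intensity distributions count minutes per day in half-open 10-mg bins
`[0,10), …, [990,1000), [1000,∞)`. MVPA minutes are computed per variant
(metric × epoch length × threshold × bout rule); 60-s epochs are block
means of twelve 5-s epochs, and the bout rule counts time inside the union
of windows of at least the bout duration whose first and last epochs
exceed the threshold and in which at least the tolerance fraction of
epochs do. The implementation reduces each window search to a suffix-
maximum scan over prefix sums ($O(n\log n)$); tests compare it against an
exhaustive $O(n^3)$ window enumeration. Default grid anchors: 70 mg (ENMO)
and 90 mg (MAD) at 1-min epochs, thresholds 30–150 mg, bouts none / 1 min /
10 min at 80%. Winsorization caps values at the stratum-specific (age band
× sex) 99.9th percentile using the interpolated type-7 quantile, pinned
for reproducibility; re-applying the cap can move the extreme by the
interpolation width between the two largest order statistics (order
$10^{-6}$ relative), so idempotence holds to that tolerance, not exactly.

## Reliability of k-day averages

How well does a k-day average stand in for the full week? For each
participant of a perfectly compliant 7-day panel (5 weekdays, 2 weekend
days), k days are drawn without replacement, averaged, and compared to the
7-day mean with a two-way single-measure ICC across participants
(absolute-agreement form by default — the conservative choice, since the
subset-vs-full comparison should be penalised for systematic shifts;
consistency is available as an option). The subset *shares its days* with
the reference, so the reliability exceeds the naive Spearman–Brown value:
under the two-level model with between-SD $\sigma_b$ and within-SD
$\sigma_w$ over a pool of $p$ days,
$$\mathrm{ICC}_k \approx \frac{\sigma_b^2 + \sigma_w^2/p}
{\sigma_b^2 + \sigma_w^2\left(\tfrac{1}{2k} + \tfrac{1}{2p}\right)},$$
which the package's simulation reproduces within Monte-Carlo error (the
closed form was validated against a brute-force simulation before being
frozen into the tests). Subsets for increasing k are nested prefixes of
one per-participant permutation, making the reliability curve monotone in
k draw by draw.

```{r icc-example}
panel <- generate_day_summary_panel(n = 500, between_sd = 4, within_sd = 2,
                                    seed = 7)
run_missing_day_simulation(panel, seed = 1)
```

## The synthetic cohort

The generator emulates what the pipeline must survive, not human
biomechanics:

* **Device**: 12-bit quantization over ±6 g (or ±8 g), so every stored
  sample is an integer multiple of 2·range/4096 ≈ 2.9 mg, with clipping at
  the range edges counted in the ground truth; raw files store the integer
  ADC counts in a documented text dialect, which preserves the
  quantization grid exactly.
* **Posture rhythm**: the longitudinal axis sits near ±90° elevation
  during a configurable night block (23:00–07:00) and 10–20° off
  horizontal by day, with 30-min smoothed transitions and a slow azimuth
  walk — the pattern the lag-24 h axis-verification step exploits.
* **Activity**: zero-mean Gaussian fluctuations whose SD follows a 24-h
  intensity profile (scaled so the nominal profile value is the expected
  epoch MAD in mg), plus sustained activity bouts logged in the ground
  truth.
* **Micro-movements**: brief postural adjustment bursts every few minutes
  during *all* worn time. A worn device is never still for a whole hour;
  without these bursts, quiet evenings and sleep fall under the 13 mg SD
  criterion and would be labelled non-wear despite being worn.
* **Non-wear**: slot-aligned episodes with a frozen random orientation and
  sensor noise only (3 mg SD default — a free parameter of this design,
  chosen as a plausible MEMS noise floor, not a published device value).
* **Still bouts**: short motionless periods at random orientations
  (device handling), which give the calibration sphere fit its coverage.
* **Calibration distortion**: the stored signal is
  $g_d\,(a_{\text{true}} + o_d)$ per axis, so the fitted correction should
  recover $1/g_d$ and $-o_d$ exactly.

Determinism: each participant's signal comes from an RNG substream derived
by a stable hash of the participant id from the cohort seed, so cohorts
are reproducible file-for-file regardless of generation order.

What passing tests on this cohort do *not* show: real gait harmonics,
device-specific noise spectra, temperature drift, or realistic behavioural
variety. The generator's role is to make every rule of the pipeline
falsifiable with known ground truth, not to claim population realism.

## Problem sizes and numerical conventions

The test suite runs the full pipeline on a 50-participant, 8-day cohort at
20 Hz — all algorithms are rate-parameterised, and 20 Hz exercises the
same code paths as the devices' native 100 Hz at desk scale; targeted
tests also run at 100 Hz. Calibration recovery uses 27 orientation-rich
1-day recordings at 20 Hz; the reliability simulation uses 5000
participants × 200 replicate draws. Summary CSVs round to 10 significant
digits so repeated runs are byte-identical; all clock arithmetic is local
civil time (stored as UTC `POSIXct`, i.e. no hidden timezone rules), with
day lengths of 23/24/25 h handled explicitly in the valid-day rule.

## Known limitations

* The posture-angle formula is this package's documented stand-in (5-s
  medians), not a published definition.
* The centered non-wear window blurs episode edges by design; segment
  accuracy near the 95% level reflects the rule, not a defect of the
  detector.
* Exact idempotence of winsorization fails at the order of the
  interpolation width (see above).
* The MVPA variant grid is a superset anchored at the literature
  cut-points; it is not a reproduction of any specific study's variant
  list.
* Calibration pools no information across recordings; each file is fit on
  its own still points.
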