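---
title: "Methods: fruit-battery and color-feature ripeness grading"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fruit-battery and color-feature ripeness grading}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(palmripe)
```

## The measurement model

Oil palm fruit ripeness is defined here by mesocarp moisture: 30% or less
is *ripe*, between 30% and 53% *under-ripe*, above 53% *unripe*
(`label_ripeness()`). Both boundaries belong to the lower class — 30%
labels ripe, 53% under-ripe — because the ripe class is anchored by the
moisture level at which oil content peaks, stated inclusively ("30% or
less"). The labeling partitions \[0, 100\] with no gaps or overlaps, which
the test suite checks on a 10,001-point grid.

A fruit pierced by zinc and copper electrodes is a galvanic cell. We model
it as an ideal electromotive force $V_i$ (volts) in series with an internal
resistance $R_i$ (ohms); the voltage across an external load $R_L$ is the
divider

$$V_L = \frac{R_L}{R_i + R_L} V_i .$$

The electrode half-reactions themselves (zinc oxidation, hydrogen
evolution at the copper electrode) are deliberately outside the model: all
their chemistry is absorbed into the two lumped parameters. Assumptions
worth stating: $V_i$ is taken constant across fruit by default (its
distribution across fruit is unknown; `cohort_spec(v_i_sd = )` adds jitter
if wanted), $R_i$ is purely resistive and stationary over the measurement,
and contact/electrode placement effects are treated as part of measurement
noise.

Because moisture is the electrolyte, $R_i$ falls as moisture rises, so
unripe fruit reads a **higher** $V_L$ at any finite load. The class
contrast is quantified per load by

$$|d_{V_L}| = \left| \frac{V_{L,\mathrm{ripe}} - V_{L,\mathrm{unripe}}}
{V_{L,\mathrm{unripe}}} \right| \times 100\%$$

applied to the *class mean* voltages (`sweep_analysis()`), not averaged
over per-pair differences: replicate readings are first averaged within a
fruit, fruit means within a class, and the statistic is computed on the two
class means. Only ripe and unripe fruit enter the sweep; under-ripe fruit
are excluded from it (they are used again for calibration and
classification). The statistic is scale invariant, so it is indifferent to
whether voltages arrive in volts or millivolts.

As $R_L \to \infty$, $V_L \to V_i$ for both classes and the contrast dies;
as $R_L \to 0$, the relative contrast approaches $R_{i,u}/R_{i,r} - 1$,
its maximum. The contrast is therefore monotonically decreasing in $R_L$
(a property test covers this), and usable loads sit on the low-resistance
plateau.

## Load selection and moisture resolution

Selection (`select_load_resistance()`) is two-staged, mirroring the
measurement workflow:

1. **Shortlist** loads whose $|d_{V_L}|$ reaches a floor (`dvl_floor`).
2. Among the shortlist, pick the load whose moisture-on-voltage
   calibration slope has the **smallest magnitude** in %/mV.

Stage 2 deserves a comment. "Finest resolution" is read as: a 1 mV
measurement error should translate into the smallest possible moisture
error, i.e. the smallest $|d(\text{moisture})/dV_L|$. This matches the
stated sensitivity criterion that slopes below 1 %/mV are acceptable.
Digitization is folded in by `moisture_resolution()`:
`percent_per_lsb = |slope| × adc_step`, with
`adc_step = drive_voltage / 2^bits` from `adc_voltage_resolution()`
(0.8 mV for a 12-bit converter on 3.3 V).

The calibration itself (`fit_moisture_regression()`) is ordinary least
squares of moisture (%) on voltage (mV). The regression direction is a
design decision: the slope then carries %/mV units directly. Fits are
delegated to `stats::lm`; the test suite checks them against an
independent normal-equations solve to $10^{-9}$ relative.

The `dvl_floor` default is 70%, appropriate for field cohorts whose
low-resistance plateau sits near 76%. The synthetic cohorts generated by
this package have a milder ripe/unripe resistance contrast (ratio ≈ 2.3,
set by the default calibration line, versus ≈ 4 in field fruit), so their
plateau sits at 49–58% and falls to ~30% at 10 kΩ. `run_pipeline()`, which
always operates on synthetic cohorts, therefore defaults to a floor of 45
— the midpoint of the gap between the plateau and the first off-plateau
load, several cohort-to-cohort standard deviations away from both groups —
and documents that field data would use 70. Ties in stage 2 go to the
smallest resistance; ties never arise in practice but a deterministic rule
keeps the selection testable.

## Color correction and the R/G feature

Photographing fruit in the field means uncontrolled lighting. The
correction model is affine in RGB: a 3×4 matrix $a$ such that

$$\begin{pmatrix} C'_R \\ C'_G \\ C'_B \end{pmatrix} =
a \begin{pmatrix} C_R \\ C_G \\ C_B \\ 1 \end{pmatrix}$$

fitted by one least-squares regression per output channel over the 16
chip pairs — observed chip colors as predictors, reference chip colors as
responses (`fit_color_transform()`). Sixteen points for four unknowns per
channel is comfortably overdetermined; a rank check rejects degenerate
charts. An affine illumination change is inverted *exactly* by this family
(verified to machine precision in tests), and for non-affine lighting the
fit is still the best affine approximation at the chips — applying it can
never increase the chip residual, a property the suite asserts seed by
seed over 100 random illuminations.

Chip localization is geometric: the chart layout gives chip cells in a
unit chart frame, and a 3×3 homography maps them into the image
(`extract_chips()`). Live AR-marker detection is a pluggable concern — any
marker detector that yields the homography can sit in front; tests and the
renderer supply it directly, so no camera stack is needed. Only the
central 60% of each cell is sampled, tolerating edge bleed and slight
pose error.

Feature extraction (`color_feature()`) runs: correct → remove background →
average → ratio. Ordering is a design decision: the flow chart of the
original workflow removes background before averaging but is silent about
where correction sits; correcting *first* keeps the fixed threshold
meaningful across lighting conditions. Background removal zeroes pixels
with all three channels above 90 (logical AND); the operation is
idempotent on the image, and foreground mask plus background partition the
frame. The feature is $R_{ave}/G_{ave}$ over foreground pixels; green
serves as a reference wavelength, as in remote-sensing vegetation indices.

Whether the average should divide by the foreground count or by all
pixels (zeroed background included) is genuinely ambiguous in the source
workflow. Both are implemented (`denominator = "foreground"` / `"all"`);
foreground-only is the default because the all-pixel mean makes the
feature depend on how much background the framing happens to include.
(The *ratio* is unaffected by the choice; the individual channel means are
not.) Pixel arithmetic is floating point throughout; clipping to
\[0, 255\] happens on transform application and quantization only on
image export (`write_image()`).

## Classification protocol

`cv_accuracy()` implements stratified, seeded 8-fold cross validation.
Three decisions are not dictated by the protocol description and are made
explicit here:

* **Stratification.** With 52 fruits in 8 folds, unstratified splits
  frequently starve a fold of a class; stratified assignment keeps class
  proportions stable. Should a training portion still lose a class (only
  possible for singleton classes), the model refits on the remaining
  classes with a warning.
* **Standardization.** Features are centered and scaled using the
  *training* portion of each fold. Load voltage (tens of mV) and the R/G
  ratio (order 1) differ by two orders of magnitude; a shared gamma grid
  across feature sets only makes sense on comparable scales.
* **Spread convention.** The reported standard deviation across fold
  accuracies divides by $k$ (population convention) by default;
  `std = "sample"` switches to $k-1$.

Gamma is carried in every grid row but only affects the RBF kernel, which
is why linear rows duplicate scores across the gamma axis. The grid is
enumerated cost-major (cost slowest, kernel fastest), and
`best_config()` maximizes accuracy, breaking ties by minimal standard
deviation (the more stable estimate), then by grid order.

## What the synthetic generator emulates — and what it does not

`generate_cohort()` reproduces the statistical structure the analysis
relies on:

* **Cohort composition** 21 ripe / 15 under-ripe / 16 unripe (so the
  ripe+unripe sweep subset counts 37), moisture uniform within class
  ranges 24–30 / 30–53 / 53–80.1%, anchored by the compositional extremes
  of ripe (24.3%) and unripe (80.1%) fruit.
* **Moisture-to-circuit link.** The generator assumes a linear calibration
  law at a calibration load (default 1 kΩ):
  $V_L^{cal} = c_0 + c_1 m$ with $c_0 = 20$ mV, $c_1 = 1.9$ mV/%, inverted
  through the divider to $R_i = R_{cal}(V_i/V_L^{cal} - 1)$. No parametric
  $R_i(m)$ law is known; this choice reproduces the observed approximately
  linear moisture-voltage scatter *by construction* and is a modeling
  assumption, not a fitted physical law. It implies unripe fruit reads
  higher voltage at every load below ~10 kΩ and that the contrast shrinks
  monotonically with load — both asserted as invariants.
* **Noise.** Two processes, separately tunable. `noise_sigma` (default
  0.1) is the *relative per-replicate measurement noise* on $V_L$; three
  replicates per reading are drawn and averaged downstream, mirroring the
  triplicate measurement protocol. `ri_sigma` (default 0.03 sdlog) is
  lognormal fruit-to-fruit scatter of $R_i$ around the calibration law,
  median-preserving. The biological scatter is kept small relative to the
  class-driven moisture signal so that the calibration relation stays
  approximately linear; a variance budget at these defaults predicts
  ordinary-least-squares attenuation of the recovered slope of about 4%,
  within the 5% band the recovery property asserts over 200 cohorts.
* **Color feature.** $R/G$ falls affinely from 1.8 at 24% moisture to 0.9
  at 80.1% (riper fruit is redder), plus independent Gaussian noise
  (`rg_sigma`, default 0.06 — slightly noisier than the battery channel,
  matching the qualitative ordering in which vision alone trails the
  battery). Because the two modalities' noises are independent, combining
  them should not lose accuracy on average — the ordering property the
  acceptance suite checks over 50 cohorts. Per-cohort comparisons use a
  0.02 tolerance: one held-out fruit is worth $1/52 \approx 0.02$
  accuracy, so differences below that are protocol granularity.
* **Scenes.** `render_fruit_image()` paints background (value 200), a
  16-chip chart placed by a known homography, and an elliptical fruit
  whose painted color realizes the sample's true $R/G$; an affine
  illumination (gains 0.9–1.1, cross-talk ±0.02, offsets ±6 when random)
  perturbs the frame, and ground truth (illumination matrix, fruit mask,
  true ratio) is returned. The default chip palette keeps every channel in
  \[115, 200\] so chart and background are both removed by the intensity
  threshold and only fruit survives into the foreground mask. Illumination
  that pushes fruit pixels past the background condition flags the render
  as contaminated rather than failing.

Not emulated: fruit surface texture and spikelets, specular highlights,
non-affine (e.g. gamma-curve or spatially varying) illumination, camera
compression artifacts, chart occlusion by the fruit, and any real
between-fruit covariance between color and moisture beyond the assumed
affine trends. Passing tests therefore demonstrate that the *pipeline*
recovers what its model family can represent — they do not validate the
circuit model or the affine illumination assumption against real fruit.
The headline field results (accuracies near 90% on 52 physical fruits)
come from measurements that were never deposited and are *not*
reproduced numerically here; what the package reproduces is the protocol
and its qualitative structure: which load wins, that resolution beats the
1 %/mV criterion, and that combined features do not underperform single
modalities.

## Numerical choices and degenerate inputs

* Load voltages are computed and stored in volts internally; tables and
  regressions use mV where slope units (%/mV) demand it.
* `fit_moisture_regression()` rejects designs with fewer than two distinct
  voltages; an all-constant response returns slope 0 with $R^2 = 1$
  (a perfect fit of a flat line, clamped to \[0, 1\] against floating-point
  drift).
* `voltage_difference_pct()` refuses a zero denominator rather than
  returning infinity.
* Chip extraction errors name the offending chip when a cell maps outside
  the image or is fully excluded by an occlusion mask.
* The SVM path guards zero-variance features (scale factor forced to 1)
  and degenerate single-class training folds (predict the constant class).
* All randomness — cohort draws, fold assignment, illumination — flows
  from explicit integer seeds; identical seed plus data yields identical
  grid tables, byte-identical fixture files, and identical manifest
  checksums.

## Problem sizes used by the test and acceptance suites

Chosen as the package's own verification scale: cohorts of n = 52 (the
study composition) throughout; 200 cohorts for slope-recovery, 100 random
illuminations on 120×160 renders for the correction properties, 50
cohorts × 18 configurations × 8 folds × 3 feature sets for the
modality-ordering property, and 50 shuffled-label cohorts of n = 800 for
the chance-level baseline. The complete suite runs in under two minutes
on one CPU.

## Known limitations

The equivalent circuit ignores electrode polarization and any capacitive
or time-dependent behavior of fruit tissue; $V_i$ is assumed
fruit-independent by default; the affine color model cannot represent
nonlinear camera response; and the synthetic cohort's class contrast is
milder than field fruit, which is why the pipeline's shortlist floor
differs from the field default (45 versus 70). Conclusions about real
fruit require real measurements; the package's value is that every stage
of that future analysis is already implemented, seeded, and tested.
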