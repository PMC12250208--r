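---
title: "Methods: masked signal detection from collective fish behaviour"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: masked signal detection from collective fish behaviour}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shoalsdt)
```

This vignette is the package's own account of the procedures it
implements: the behavioural metrics, the two-scale signal-detection
analysis, the acoustic characterisation, and the synthetic-data generator
that stands in for unavailable raw trajectories. It also records the
design decisions taken where the underlying methodology leaves choices
open, and what the passing test suite does and does not establish.

## 1. Group kinematics

A trial is a 30 frames/s record of five fish in a 0.86 × 0.308 m arena:
positions $(x_i(n), y_i(n))$ in metres and an axial body angle in
$[-90°, 90°]$ per fish per frame. Three group metrics are computed per
frame and averaged into 1-s bins (trailing partial bin discarded):

* **Group speed** (m/s): Euclidean displacement of the shoal centre
  $\bar X(n)$ (the component-wise mean of the five positions) between
  consecutive frames, times the frame rate. The first frame has no
  predecessor and copies the second frame's value — one padded frame in
  90,000 for a full trial, chosen over dropping the frame so that series
  lengths stay aligned to the video.
* **Inter-individual distance** (m): $\sqrt{sd_x^2 + sd_y^2}$ with
  *population* (divisor $n$) standard deviations across the five fish.
  Algebraically this equals the root-mean-square distance of the fish
  from the shoal centre; the test suite verifies the identity on random
  configurations. The plain mean distance to the centre is available via
  `method = "mean_dist"` — the two definitions differ slightly (RMS
  weights outliers more) and the SD form is the default because it is the
  one defined operationally ("combining the standard deviations of the
  locations on the x and y axes").
* **Alignment** (degrees): standard deviation of the five body angles,
  treated as linear quantities with the sample (divisor $n-1$) convention;
  the divisor is configurable since the operational definition does not
  fix it. Lower values mean stronger alignment. Angles are axial
  (head-to-tail line), so two nearly parallel fish can be coded −89° and
  +89°; the linear SD is then badly inflated. `alignment()` warns whenever
  an angle pair differs by more than 90°, the signature of that fold. A
  circular (axial) dispersion would avoid the artefact but would not be
  the statistic the metric is defined as, so the linear SD is kept and the
  warning makes the failure mode visible.

**Blocked summaries.** For baseline-deviation scoring, 1-s series are cut
into consecutive 30-s blocks and summarised by the median and the raw
(unscaled) median absolute deviation. A block *deviates* from the control
when the two `median ± MAD` intervals are disjoint; the deviating
fraction and per-block direction are reported. The default block count is
21 (10-min exposure plus the onset-containing window): reported deviation
percentages in this design are multiples of 1/21 (4.76, 9.52, 14.3, 23.8,
38.1, 66.7 %), which is what fixes the convention; an 11-block variant is
available through the `window`/`n_blocks` arguments for compatibility
with coarser summaries.

## 2. Startle scoring

Visual startle scoring is replaced by an automated detector with
configurable thresholds. A fish is flagged when, within the first
`window_s = 1` s after stimulus onset, its instantaneous speed exceeds
`speed_factor = 4` times its own pre-onset median speed *and* its
movement heading changes by at least `min_turn_deg = 45°` within 0.5 s.
The conjunction mirrors the operational definition of a startle — a burst
swim at an altered angle — and the per-fish baseline makes the speed
criterion self-normalising. These thresholds are package inventions, not
measured quantities; they were chosen so that simulator-injected bursts
are recovered at ≥ 99% with no false positives on calm fixtures, and the
test suite holds them to that.

Continuous startle runs are counted against the pulse schedule (1 s ON :
2 s OFF): the count is the number of consecutive pulses, *starting from
pulse 1*, whose window `[pulse start, pulse start + 1 s + 0.5 s]`
contains at least one startle; the first empty pulse ends the run, and a
run that begins at pulse 2 scores zero (the quantity is anchored at
stimulus onset). The 0.5-s grace window reflects that startles were
observed to last under 0.5 s and that a response to a pulse can spill
past its nominal end; whether an OFF-interval startle should credit the
preceding pulse is not fixed by the source methodology, so the grace
length is an argument.

## 3. Fine-scale classification: GLS slopes vs the normative fit

For each trial, the 1-s inter-individual-distance series over the 10-min
exposure is regressed on time, $y = \beta_0 + \beta_1 t$, by generalised
least squares with AR(1) errors (REML, via `nlme::gls`). AR(1) is the
minimal standard structure for 1-s behavioural series — the requirement
is only to "account for autocorrelation" — and `corr = "none"` reduces
the fit exactly to ordinary least squares (verified against the closed
form to 1e−8). The 95% interval uses the $t_{0.975,\,n-2}$ quantile; with
$n = 600$ the df convention is immaterial but is stated for
reproducibility. Degenerate inputs (constant series, noiseless lines) are
detected by a residual-variance threshold of $10^{-10}$ relative to the
response scale and returned as exact fits with zero standard error rather
than passed to the optimiser.

The control reference — the **normative fit** — is the same GLS applied
to the point-wise mean of the control trials' series, matching the single
"control group average" regression line the procedure is defined by.
Inverse-variance pooling of per-trial slopes is offered as an
alternative (`pooling = "ivw"`). A trial *deviates* when its slope CI and
the normative CI are disjoint (trial upper bound below the control lower
bound, or trial lower bound above the control upper bound). Deviation in
either direction counts as a response — the rule is two-sided — with the
direction recorded separately. Outcomes follow the standard contingency:
signal present and deviated = hit; absent and deviated = false alarm; and
so on. Control trials are classified against the full-sample normative
fit by default; since a control trial contributes to the reference it is
judged against, a leave-one-out flag is provided, defaulting off because
the full-sample variant is the simpler reading of the procedure and the
difference is second-order at ten control trials.

Fine-scale classification uses inter-individual distance only (the
`metric` argument admits the others): cohesion is the channel through
which the tone remains detectable under masking, and it is the parameter
the fine-scale detection metrics are defined on.

## 4. Signal detection theory

With $N_s$ signal and $N_n$ noise trials, rates at the boundary are
corrected — $0 \to 1/(2N)$, $1 \to 1 - 1/(2N)$, interior rates untouched
(the correction is conditional, not the unconditional log-linear form) —
and

$$d' = z(\mathrm{HR}) - z(\mathrm{FAR}), \qquad
  c = -\tfrac{1}{2}\,(z(\mathrm{HR}) + z(\mathrm{FAR})).$$

$z = \Phi^{-1}$ is the standard inverse normal; this sign convention
reproduces every printed value of the study the package emulates to two
decimals (e.g. 10/10 hits vs 0/10 false alarms at $N = 10$ gives
$d' = z(0.95) - z(0.05) = 3.29$; 1/10 vs 0/10 gives $d' = 0.36$,
$c = 1.46$). The criterion formula is the standard equal-variance
definition. ROC artifacts provide $(FAR, HR)$ points plus iso-$d'$ curves
$HR = \Phi(d + z(FAR))$ and iso-$c$ curves $HR = \Phi(-2c - z(FAR))$.
The round-trip identity — rates generated as
$HR = \Phi(d/2 - c),\ FAR = \Phi(-d/2 - c)$ recover $(d, c)$ to 1e−10 —
is part of the acceptance suite.

In the pipeline, each treatment's noise side is the matching
noise-condition control (AMB-C for ambient treatments, MASK-C for
masked): a masked tone should be judged against the masked soundscape.
Consequently a control trial's classification is reused across the three
same-condition treatments — the natural consequence of a matching-control
design with per-treatment tables.

## 5. Acoustics

* **Stimuli.** `synth_tone()` gates a sinusoid (170 Hz default) ON/OFF
  and scales it so the RMS over ON segments matches the requested SPL re
  1 µPa; OFF samples are exactly zero. `synth_masker()` band-passes
  Gaussian white noise (120–3000 Hz, order-8 Butterworth, 12.8 kHz) and
  scales to the target broadband SPL. The order-8 band-pass is realised
  as two cascaded order-4 sections: the direct order-16 transfer function
  is numerically unstable at these normalised band edges, while the
  cascade keeps the asymptotic 48 dB/octave skirts (verified: ≥ 40 dB
  attenuation one octave below the lower edge).
* **PSD.** Welch averaging with a periodic Hann window and fractional
  overlap (defaults 8192 / 91.5% for stimulus characterisation, 1024 /
  50% for field mapping at 25.6 kHz, i.e. 3.125-Hz and 25-Hz bins). The
  one-sided density integrates to the signal variance (Parseval, tested
  to 5%).
* **Band measures.** One-third-octave edges use base-2 ratios
  $f_{lo,hi} = f_c\,2^{\mp 1/6}$ (151.5–190.8 Hz at 170 Hz; the base-10
  convention differs by under 0.1% and is not offered). Band-limited RMS
  measures (`spl_rms(band=)`, `snr_map`) use an exact zero-phase FFT
  brick-wall filter: IIR designs of such narrow normalised bands are
  numerically unreliable (an order-4 Butterworth of the 151–190 Hz band
  at 25.6 kHz shows ~2× gain error at centre), whereas the brick-wall has
  unit in-band gain by construction. The Butterworth remains the
  *synthesis* filter for the masker, as specified; the brick-wall is a
  measurement device.
* **Particle acceleration.** From $a = -\nabla P / \rho$: per axis, the
  RMS over time of adjacent-point pressure differences, divided by the
  spacing and by $\rho$ (1000 kg/m³ default). Forward differences are
  attributed to the staggered interior grid, so component maps have one
  fewer point along their axis and the total — the root sum of squares of
  the three components, i.e. the magnitude of orthogonal components — is
  reported on the $(n_x-1)(n_y-1)(n_z-1)$ grid. For a plane wave the
  finite difference carries the factor $2\sin(k\Delta x/2)/(k\Delta x)$;
  at $k\Delta x \le 0.05$ the bias is under $10^{-4}$ and the test suite
  confirms the analytic $A k/(\rho\sqrt2)$ within 1% and second-order
  convergence under grid refinement. dB values use 1 µm/s² as reference
  (configurable; a re-1-mm/s² variant exists in parts of the source
  literature and is treated as a units inconsistency there). A uniform
  field yields zero acceleration with dB flagged undefined (−Inf).

The pressure-difference series are simultaneous by construction in the
simulator; with sequential single-hydrophone field measurements the same
estimator applies but phase consistency between points is then an
assumption, not a guarantee.

## 6. The synthetic-data generator

The generator is deliberately structural rather than biomechanical: it
reproduces the statistical features the analysis consumes, and nothing
more.

* The shoal centre follows a persistent path (heading random walk,
  mean-reverting speed).
* Each fish holds a station along the tank length with
  Ornstein–Uhlenbeck positional wander (time constant 30 s), so the group
  is spread lengthwise as in a long narrow arena.
* The slow (centre + station) component passes through a smooth wall-bias
  ("thigmotaxis") map that turns broad occupancy into the wall-heavy,
  arcsine-like occupancy of carp in bare tanks. This is what lets the
  positional spread exceed the uniform-occupancy ceiling
  ($L/\sqrt{12}$); the map is applied to the slow component only so that
  instantaneous speeds are not distorted.
* Body angles combine a group orientation (OU around the tank axis) with
  individual angular wander, folded axially into $[-90°, 90°)$.
* At onset each fish startles independently with the treatment's
  probability: a 0.3-s dash at 2.5 m/s whose heading kinks sharply away
  from the path (and again mid-burst — escape paths are erratic, and the
  kink is what a turn-based detector keys on).
* Treatment effects multiply the speed mean, the positional spread and
  the angular spread; they rise over ~5 s after onset (an instantaneous
  multiplier would teleport fish between frames) and decay back to
  baseline with the configured half-life. Default multipliers are the
  ratios of reported exposure medians to control medians; half-lives
  encode that ambient-condition effects persisted longer than masked
  ones.
* Positions are reflected at the walls; every position is in-bounds at
  every frame, and same-seed trials are bit-identical. Per-trial seeds
  are split from the master seed by a single `sample.int` draw per trial.

Internal calibration constants were fixed once so that ten control trials
reproduce the emulated study's control medians: simulated medians 0.203
m/s (target 0.21 ± 0.03), 0.288 m (target 0.31 ± 0.04), 37.6° (target
37.8). The cohesion metric sits ~0.02 below its target: the wall-heavy
occupancy bounds the achievable spread, and the divisor-$n$ SD over five
fish is biased low by the factor $\sqrt{(n-1)/n}$; both effects are
structural and were accepted rather than compensated by further shaping.

Default fixture trials use a 60-s baseline plus the 600-s exposure; the
analysis consumes only a pre-onset baseline window and the exposure, so
the full 30-min acclimation (`baseline_s = 1800`) adds nothing but
runtime.

**What passing tests do not show.** The generator makes no claim of
hydrodynamic, sensory or social realism: there is no swimming kinematics
between frames, no auditory periphery, no 3-D structure (the analysis is
2-D overhead-view), and real tracked trajectories carry measurement noise,
identity swaps and occlusions that the pipeline is not tested against.
Tests passing on simulated data establish that the *procedures* are
implemented correctly and recover known generating parameters — not that
the biological effect sizes are as the defaults encode them.

## 7. Parameter recovery and problem sizes

The recovery experiment draws per-trial deviation outcomes at generating
probabilities 0.95 (signal) and 0.05 (noise), 10 + 10 trials per
replicate, 200 replicates, and runs them through the classification →
contingency → SDT chain. Pooled over replicates the rates recover the
generating $d' = 3.29$ within ±0.15. The *mean of per-replicate* $d'$ is
a different statistic: the $1/(2N)$ boundary correction caps each
replicate's contribution, and exact binomial enumeration puts its
expectation at 2.914 at these settings; the suite asserts that value too.
Replicates are drawn at the classification level because the quantity
recovered is a function of outcome counts alone; one full
trajectory-level experiment (80 trials) is run end-to-end separately to
pin the composition of the stages.

Monte-Carlo problem sizes used by the suite: 1000 replicates × 600
observations for AR(1) CI coverage (nominal 95%, accepted band
0.93–0.97); 10,000 random CI pairs for the classification-rule oracle;
1000 random $(d, c)$ pairs for the SDT round trip; 200 simulated trials
for startle-probability convergence; 100 replicates for the
null-indistinguishability property.

## 8. Known limitations

* The linear alignment SD inflates near the axial fold; the warning
  flags it but the number is still reported.
* The GLS slope summarises a monotone trend; non-monotone responses
  (transient cohesion spikes) can have near-zero slope and be missed —
  a limitation of the procedure itself, inherited deliberately.
* `snr_map` with RMS-only grids ignores the band argument's spectral
  selectivity (it needs time series to band-filter).
* The startle detector is a proxy for visual scoring; its thresholds are
  calibrated against the package's own simulator, not against scored
  video.
* WAV I/O is minimal (mono, float32 or PCM16) and uses a YAML sidecar for
  pascal calibration rather than embedded metadata.
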