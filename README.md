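# shoalsdt

Signal detection analysis of collective fish responses to masked acoustic
stimuli.

## The problem

Playback experiments ask whether fish can detect a tonal signal when it is
partially masked by broadband noise — a question central to acoustic
deterrents at hydropower intakes and to predicting the impact of
anthropogenic noise. The experimental design this package analyses exposes
groups of five fish to a 170-Hz pulsed tone (1 s ON : 2 s OFF) at three
sound pressure levels, under either ambient background noise or an added
120–3000 Hz masking noise, with ambient and masked no-tone controls
(8 treatments × 10 trials × 5 fish, filmed at 30 frames/s).

Responses are scored at two scales and pushed through the same
signal-detection framework:

* **Coarse scale** — did any fish startle within the first second of the
  tone? Each trial is a yes/no detection decision.
* **Fine scale** — did the group's *inter-individual distance* (cohesion)
  trend over the 10-min exposure deviate from the control baseline? A
  per-trial generalised least squares (GLS) slope, with AR(1) errors to
  absorb the autocorrelation of 1-s behavioural series, is compared to the
  pooled control ("normative") fit: the trial deviates when the two 95%
  confidence intervals are disjoint.

Trial outcomes (hit / miss / false alarm / correct non-response) are
tallied per treatment, rates at the 0/1 boundary are corrected by
`1/(2N)`, and the standard equal-variance measures follow:

```
d' = z(HR) − z(FAR)          (discriminability)
c  = −(z(HR) + z(FAR)) / 2   (response criterion; >0 = conservative)
```

with `z = Φ⁻¹` the inverse standard normal. ROC artifacts (points,
iso-d′ and iso-c curves) come out plot-ready.

The package also characterises the sound field: Welch power spectral
density, RMS sound pressure level (dB re 1 µPa), one-third-octave bands
(the auditory critical band, `170·2^(±1/6)` ≈ 151–191 Hz), per-point SNR
maps on the 17 × 6 × 3 hydrophone grid, and particle acceleration
`a = −∇P/ρ` by finite differences of the gridded pressure field.

Because raw trajectories from such experiments are rarely deposited, a
seeded synthetic-data generator emulates the full design — calibrated so
control trials reproduce the study's control medians (group speed
0.21 m/s, inter-individual distance 0.31 m, alignment 37.8°) — so every
stage is exercisable and testable offline.

## Worked example

```r
library(shoalsdt)

cfg    <- sim_config(n_trials_per_treatment = 10, seed = 42)
ds     <- simulate_experiment(cfg)        # 80 seeded trials
report <- run_analysis(ds, seed = 42)     # metrics -> startle -> GLS -> SDT

report$sdt[["AMB-INT.coarse"]]
#> <sdt_result> AMB-INT coarse: HR = 0.950*, FAR = 0.050*, d' = 3.29, c = 0.00
#>   (* boundary rate corrected by 1/(2N))

report$sdt[["MASK-HIGH.fine"]]
#> <sdt_result> MASK-HIGH fine: HR = 0.900, FAR = 0.300, d' = 1.81, c = -0.38

report$normative$AMB      # pooled ambient-control regression ("normative fit")
#> <slope_ci> y = 0.2867 + -6.99e-06 t; +/- s.e. = 2.59e-06;
#>            CI [-1.208e-05; -1.897e-06]; AR1 = 0.271; n = 600

round(third_octave_band(170), 1)
#>  f_lo  f_hi
#> 151.5 190.8
```

Reading the output: at the intermediate tone level under ambient noise
every simulated trial is detected (10/10 startle hits, 0/10 control false
alarms; rates corrected off the boundary to 0.95/0.05), giving the ceiling
discriminability d′ = 3.29 with an unbiased criterion. Under masking the
startle channel collapses, but the fine-scale cohesion channel still
discriminates (d′ = 1.81 here), mirroring the partial-masking pattern the
design was built to expose. `plot(report$roc$fine)` draws the ROC with
reference iso-d′ and iso-c curves.

Acoustic characterisation runs the same way from gridded pressure
fixtures:

```r
sig <- make_pressure_fixture("tone_plus_noise", list(snr_db = 15), seed = 1)
noi <- make_pressure_fixture("noise",          list(snr_db = 15), seed = 1)
field <- run_acoustics(sig, noi)   # SPL map, banded SNR map, accel map
```

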