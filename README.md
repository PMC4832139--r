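# psykernel

Simulation and analysis toolchain for **continuous visual
displacement-detection experiments** — the paradigm in which identical
circles drift across a display at constant speed and, every few seconds, one
of them is abruptly displaced from its linear trajectory. Observers signal
detection at three latency levels: reflexive *express saccades* (25–150 ms),
*regular saccades* (150–250 ms), and *explicit* button presses. The package
is aimed at visual-psychophysics and computational-neuroscience researchers
who want to run, or re-analyze, this class of "deviant-stimulus" experiments
from eye-tracking and button-press logs.

## What it computes

The core statistic is the **psychophysical kernel**: each trial's
displacement vector **d** is mapped into the motion-normalized frame,

> x = R(−θ) d / s,  θ = direction of pre-displacement motion, s = speed,

so that +x is "along the predicted trajectory". Detected and undetected
trials yield two kernel-density estimates on [−0.5, 0.5]²; the rectified
difference D = max(0, f_undetected − f_detected), renormalized, is sampled
(1000 points) and fitted with a 2D Gaussian. The covariance ellipse of that
Gaussian is the kernel — displacements inside it tend to be missed — and is
summarized by

* **area** = π·√det Σ (1-SD ellipse),
* **eccentricity** = √(1 − (b/a)²), a ≥ b the semi-axes,
* **shift** = ‖center‖,
* **orientation** = major-axis angle vs +x, in (−90°, 90°].

Around this sit: a **stimulus simulator** (10 items, 18°/s, bouncing
boundaries, displacement schedule with uniform 2–4 s gaps, counterbalanced
orientations, 0.5°–8° amplitude grid), a **synthetic observer** (ground-truth
logistic-in-Mahalanobis detection kernel, ballistic saccades, blinks,
presses) so every stage is testable without human data, a **saccade
detector** for 60 Hz gaze (adaptive threshold = mean + 1 SD of acceleration
in the 2 s pre-displacement window, ±22.5° direction cone, express/regular
latency classification), **trial binning** into mutually exclusive detection
categories, and **group statistics** (one-way repeated-measures ANOVA with
Mauchly's test and Greenhouse–Geisser correction, paired t tests).

## Worked example

Two runs' worth of trials, a synthetic observer, and the full chain:

```r
library(psykernel)

stim <- run_session(scene_config(), n_trials = 320, seed = 1)
stim
#> <stimulus_log> 320 displacement events, 957.3 s, 10 items @ 18 deg/s

resp <- simulate_responses(stim, observer_config(), seed = 2)
det  <- detect_session_saccades(resp$gaze, stim$displacements)
outcomes <- bin_trials(stim$displacements, det$saccades, resp$presses)
round(detection_rates(outcomes), 2)
#>     express_only     regular_only    explicit_only  express+regular
#>            12.81            10.00            15.00             2.50
#> express+explicit regular+explicit   multiple_other       undetected
#>             4.38             4.06             0.94            50.31

k <- kernel_pipeline(outcomes, stim$displacements, "explicit_only", seed = 3)
k
#> <psy_kernel> center (0.036, -0.007)  area 0.0092  ecc 0.806  shift 0.036  orient -2.7 deg  (n=209)

res <- pre_post_saccade_counts(resp$gaze, stim$displacements)
sprintf("pre/post validity: t = %.2f, df = %d, p = %.3g",
        res$t_test$t, res$t_test$df, res$t_test$p)
#> "pre/post validity: t = 3.24, df = 319, p = 0.00134"
```

Reading the output: ~50% of displacements go undetected; the fitted
explicit-detection kernel is elongated along the motion axis
(eccentricity 0.81, orientation ≈ 0°) with a small forward shift — the
observer's ground-truth kernel here is center (0.05, 0), eccentricity
√3/2 ≈ 0.87, so the pipeline recovers it closely from 320 trials. The
pre/post t confirms that target-directed movements cluster after
displacements (a single synthetic session; pooled multi-subject data gives
much larger t). With per-subject kernel tables for the three pure response
categories, `kernel_stats()` produces the ANOVA (+ sphericity correction)
and post-hoc tables.

A command-line front end wraps the same stages
(`inst/cli/psykernel simulate|detect|kernel|stats --...`).

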