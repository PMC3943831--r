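---
title: "Ankle moment–angle loop analysis: models, conventions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ankle moment-angle loop analysis: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The quantities

Over the stance phase of walking the ankle traces a loop in the
moment-versus-angle plane. Three derived quantities summarise it:

* **Quasi-stiffness** `K = dM/dθ`, estimated per sub-phase as the slope of the
  ordinary least-squares line of the mass-normalised moment on the angle
  (N m kg⁻¹ rad⁻¹), with an intercept (loops do not pass through the origin)
  and R² as the linearity diagnostic. Unlike a true mechanical stiffness it
  describes the net task-level behaviour of muscles plus passive structures.
* **Work**: the signed trapezoidal integral of moment over angle per
  sub-phase, and the net loop work `W_total = |W_PP| − |W_CD|`. The CP term is
  excluded from the net by this accounting rule; it is an order of magnitude
  smaller and is always reported separately.
* **Power** `P = M·ω` (here realised as `−moment_norm · ω`, see sign
  conventions), summarised as the stance peak and mean.

Stance is divided into **controlled plantarflexion** (CP, heel strike to the
early plantarflexion trough), **controlled dorsiflexion** (CD, to the
dorsiflexion maximum; power non-positive, energy absorption) and **powered
plantarflexion** (PP, sustained positive power to toe-off; energy return and
active push-off).

## Sign conventions

Published conventions are ambiguous: the angle and moment are described as
dorsiflexion-positive, yet reported CD quasi-stiffness is positive ≈ 5, which
requires the loop to be plotted with the plantarflexor moment positive. The
package therefore fixes:

* angle: dorsiflexion-positive, zero where the foot is perpendicular to the
  tibia; stored in degrees in trial files, radians after preprocessing;
* moment: **plantarflexor-positive** for loop, stiffness and work
  computations (so CD and PP slopes are positive);
* power: internal-moment pairing `P = −moment_norm · ω`, so CD power is
  negative (absorption) and PP power positive (generation).

With these choices the energy-signed per-phase works are obtained by
integrating `−moment_norm` over the angle; their sum over a *closed* loop
equals the shoelace (signed polygon) area of the plantarflexor-positive loop,
counter-clockwise positive. `analyze_trial()` computes both and logs their
difference; on real (open) stance paths they differ by exactly the polygon
closure segment, which is reported, not hidden.

## Preprocessing

* **Zero-lag filtering.** "Zero-lag 6th-order Butterworth, 10 Hz" is realised
  as a 6th-order digital Butterworth applied forward and backward (effective
  12th-order magnitude, exactly zero phase), with no cutoff-correction
  factor; `order = 3` gives the alternative reading (3rd order twice). Edge
  transients are handled by odd-reflection padding of `3·(order+1)` samples,
  and each pass filters about the first padded value, so a constant series is
  a fixed point (DC gain exactly 1). The analytic dual-pass magnitude
  response is exposed as `butterworth_gain()`; the measured 25 Hz attenuation
  of a sampled sinusoid matches it to ~1e-9.
* **Stance detection**: first/last run of ≥ 3 samples with vertical GRF above
  3 % of body weight.
* **Stance-time normalisation**: linear interpolation onto 101 equally spaced
  points (0–100 % stance, the field convention; the count is configurable).
* **Angular velocity**: central differences, with second-order one-sided
  stencils at the boundaries — the lowest-surprise choice for uniformly
  sampled series.

A band-limited (< 10 Hz) noise-free signal passes through filtering plus
resampling with metric changes below 0.1 %. The generated gait trajectories,
however, are *not* band-limited: the CP dip lasts only ~50 ms, so the
prescribed 10 Hz cutoff genuinely attenuates part of it and shifts the
filtered trough by ~2 samples (verified to be passband distortion, not an edge
artefact, by embedding the series in long constant lead-ins). Consequences:

* machine-precision validation (stiffness recovery < 1e-6, energy bookkeeping
  < 1e-9) is performed on the unfiltered native-grid path, which isolates the
  estimators from the filter;
* the segmentation robustness Monte Carlo compares noisy trials against the
  noise-free trial processed identically, isolating noise sensitivity from
  the systematic filter shift;
* CP-phase regressions have low R² (≈ 0.3–0.5 across the presets) — the CP
  window is short (~5 samples at 100 Hz), poorly resolved at 10 Hz, and its
  reported stiffness is correspondingly variable. This mirrors what is seen
  in human data and is one reason CP work is excluded from `W_total`.

## Segmentation rules

* CP trough: global angle minimum within the first 35 % of stance (CP is
  short; the window must not reach the toe-off plantarflexion). A monotone
  angle raises `"no CP trough"`.
* CD→PP boundary: the descriptions "maximum dorsiflexion" and "power turns
  positive" can disagree by a few samples. The **power crossing is
  authoritative** (it guarantees power ≤ 0 in CD and > 0 in PP): the first
  run of ≥ 3 positive-power samples (persistence suppresses zero-crossing
  chatter at 100 Hz), searched within ±10 % of stance around the angle
  maximum, then moved one sample up if the next sample is still higher —
  the boundary sample is the local dorsiflexion peak. `cd_rule = "angle"`
  selects the plain angle-maximum rule; the sample distance between the two
  definitions is recorded in the segmentation diagnostics.
* Trials whose power never goes sustainedly positive (possible at very slow
  speeds) are reported as `"no PP onset"` failures, never guessed.
* Net work is robust to the exact CD/PP split: `|W_PP| − |W_CD|` equals the
  signed work sum over CD ∪ PP whenever CD absorbs and PP generates, so
  moving the boundary by a sample transfers area between the terms without
  changing their difference.

## The synthetic stance generator

`generate_trial()` emulates a 100 Hz stance recording with known ground
truth. It is a model of the *statistical structure* the analysis assumes, not
a musculoskeletal simulation.

* **Kinematics**: half-cosine angle segments 0 → θ_CP-trough → θ_CD-peak →
  θ_toe-off, C¹ at the switches (zero angular velocity at each join), with
  the switch times snapped to the sampling grid so ground-truth indices are
  exact integers.
* **Kinetics**: per phase `M = K_phase·(θ − anchor) + c·ω`, plus a half-sine
  actuator bump confined to PP and scaled analytically so it injects exactly
  `pushoff_work`. Anchors solve (i) moment continuity at both switches and
  (ii) equality of elastic energy stored over CD and returned over PP. With
  (ii), and because trapezoidal integration of a moment linear in θ is exact,
  the discrete net loop work of the noise-free trial equals
  `injected − dissipated` to machine precision — the generator's energy
  ledger is exact by construction, which is what makes end-to-end bookkeeping
  tests meaningful. A side effect of (ii) is a slightly negative toe-off
  moment, consistent with the geometry implied by published stiffness and
  work magnitudes (the PP sweep is wider than the CD sweep).
* **GRF**: a double-hump curve (`1.30·sin(πτ) + 0.28·sin(3πτ)` times body
  weight, peaks ≈ 1.12 BW), strictly positive inside stance and exactly zero
  at the endpoints; only its on/off support matters for stance detection.
* **Noise**: additive Gaussian on the written angle (SD 0.25°) and
  mass-normalised moment (SD 0.03 N m kg⁻¹) — measurement-scale noise under
  which the CD stiffness estimate stays within ~0.5 % of truth and CD/PP R²
  remain above 0.9.
* **Speed presets** (fixed study conditions, chosen once to mimic the
  qualitative trends of adult gait): stance durations 0.85/0.78/0.70/0.60 s;
  K_CD 4.6/4.5/5.5/5.8 (CD stiffens with speed); K_PP ≈ 4.5–4.8;
  K_CP −0.6…−0.2; damping 0.08/0.05/0.03/0.02 N m s kg⁻¹ rad⁻¹ (the damping
  contribution fades with speed) and push-off energy 0.035/0.115/0.195/0.395
  N m rad kg⁻¹ (an active source grows with speed), so the net loop work runs
  ≈ −0.05, +0.05, +0.15, +0.35 N m rad kg⁻¹ across the four speeds and the
  loop direction flips from clockwise to counter-clockwise. These are preset
  modelling choices, not claims about any particular data set.
* **Cohorts**: per-subject multiplicative Gaussian effects — one common
  factor on all three stiffnesses (SD 0.12, so within-subject correlation
  across speeds is real), stance duration (SD 0.05), push-off (SD 0.15),
  damping (SD 0.10), body mass N(67.6, 10.2) kg — with all trial seeds
  derived deterministically from one master seed.

What the generator does **not** emulate: marker/inverse-dynamics error
structure (correlated, non-Gaussian), multi-segment foot kinematics, swing,
inter-trial variability within a session beyond iid noise, and any
nonlinearity within a sub-phase (each phase is linear-elastic by
construction). Passing tests therefore demonstrate the correctness of the
estimators and pipeline plumbing under the stated assumptions — not that the
pipeline is robust to every pathology of real motion-capture data.

## Statistics

* `rm_anova()` implements the one-way within-subject decomposition explicitly
  (`SS_total = SS_subjects + SS_conditions + SS_error`,
  `F = MS_cond/MS_err` on `(k−1, (k−1)(n−1))` df) so the SS terms are
  exposed and testable against a brute-force loop oracle (and against
  `stats::aov`). No sphericity correction is applied by default;
  Greenhouse–Geisser is available behind `gg_correction`. Type-I error at
  α = 0.05 calibrates to 0.046–0.047 over 2000 null simulations.
* Pairwise contrasts: paired t tests over all 6 speed pairs, Bonferroni
  factor fixed at 6, capped at 1.
* Aggregation is complete-case: subjects missing a speed are dropped with a
  warning and the count reported; repeated trials are averaged within subject
  before any cell statistics.
* `ks_normality()` tests against a normal with estimated parameters and
  reports the asymptotic p (flagged, since estimating parameters makes it
  conservative — the Lilliefors caveat); statistical suites differ in whether
  they apply the correction silently, so `method = "lilliefors"` exposes the
  corrected variant too.

## Problem sizes

The packaged checks use 100-seed Monte Carlos for recovery, hysteresis
direction and peak-power ordering, 200 noisy trials for segmentation
robustness, 2000 simulations for null calibration, and 200 replicate
20-subject cohorts for the power of the fast-vs-slow CD-stiffness contrast —
sizes at which the binomial uncertainty of each rate is well below the margin
to its threshold.

## Known limitations

* Human-subject means from any particular study are not reproducible here:
  only internal arithmetic and qualitative speed trends are testable against
  synthetic cohorts.
* The CP trough position inherits a ~2-sample systematic shift from the
  prescribed 10 Hz filter (above); CP stiffness should be interpreted with
  its low R² in mind.
* `W_total` follows the `|W_PP| − |W_CD|` rule even though the loop area also
  contains the (small) CP contribution; the shoelace diagnostic quantifies
  the difference per trial.
* The generator's inter-subject jitter model is a stand-in chosen for
  plausibility (published tables report SDs only), not an inference from
  data.
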