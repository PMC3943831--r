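# ankleloop

Ankle moment–angle loop analysis for the stance phase of walking.

During stance, the ankle joint traces a loop in the moment-versus-angle plane.
Its local slope is the **quasi-stiffness** `K = dM/dθ` (N m kg⁻¹ rad⁻¹), its
enclosed area is net mechanical **work** (N m rad kg⁻¹), and its traversal
direction tells whether the joint net-absorbs (clockwise) or net-generates
(counter-clockwise) energy. These quantities, resolved by stance sub-phase and
walking speed, are the primary design inputs for spring, damper and actuator
selection in ankle–foot prostheses. `ankleloop` implements the full analysis
chain for researchers in gait biomechanics and rehabilitation engineering:

* **Preprocessing** — zero-lag (forward–backward) 6th-order Butterworth
  low-pass filtering at 10 Hz, stance detection from the vertical ground
  reaction force, stance-time normalisation to 101 points, mass normalisation,
  angular velocity by central differences, and joint power `P = -M·ω`
  (plantarflexor-positive moment paired with dorsiflexion-positive velocity,
  so mid-stance absorption is negative and push-off generation positive).
* **Sub-phase segmentation** — controlled plantarflexion (CP: heel strike to
  the early-stance plantarflexion trough), controlled dorsiflexion (CD: to the
  dorsiflexion maximum, power non-positive), powered plantarflexion (PP: from
  the sustained positive-power crossing to toe-off).
* **Mechanics** — per-phase quasi-stiffness by least squares with R², signed
  per-phase trapezoidal work, net loop work `W_total = |W_PP| − |W_CD|`, an
  independent shoelace-polygon area cross-check, and peak/mean stance power.
* **Cohort statistics** — subject×speed aggregation into "mean (SD)" tables,
  one-way repeated-measures ANOVA with Bonferroni-adjusted pairwise contrasts,
  and Kolmogorov–Smirnov normality checks (Lilliefors variant available).
* **Synthetic gait generator** — a phase-switched spring–damper–actuator
  stance model with exact, machine-precision energy bookkeeping, used as
  ground truth for validating every stage of the pipeline.

## Worked example

```r
library(ankleloop)

params <- speed_presets()$normal        # one of four walking-speed presets
gen    <- generate_trial(params, subject_id = "S01")
pt     <- process_trial(gen$trial)      # filter, crop, resample, power
metrics <- analyze_trial(pt)            # segment + stiffness/work/power
print(metrics)
```

```
<trial_metrics> S01 [normal]
  K (CP/CD/PP): -0.692 / 5.473 / 4.451; R^2: 0.445 / 0.999 / 0.968
  |W| (CP/CD/PP): 0.001 / 0.209 / 0.356; W_total = 0.146 N m rad kg^-1
  peak power 4.111, mean stance power 0.210 W kg^-1
```

The CD limb of the loop is stiff and near-linear (K ≈ 5.5, R² ≈ 1); CP is
short and noisy (low R², small |W|); push-off returns more energy than
mid-stance absorbed, so the net loop work is positive at normal speed.

A full cohort — 20 subjects, four speeds, repeated-measures test on the CD
quasi-stiffness:

```r
cohort  <- generate_cohort(20, seed = 1)
rows    <- lapply(names(cohort$trials), function(s)
             metrics_row(analyze_trial(process_trial(cohort$trials[[s]]))))
summary <- run_summarize(do.call(rbind, rows))
print(summary$anova$k_cd)
```

```
<rm_anova k_cd> F(3, 57) = 1118, p = 1.388e-50 (n = 20)
                pair mean_diff     p_raw p_bonferroni
   very_slow vs slow    0.1019 3.060e-04    1.836e-03
 very_slow vs normal   -0.9134 9.034e-20    5.421e-19
   very_slow vs fast   -1.2302 2.247e-19    1.348e-18
      slow vs normal   -1.0153 1.977e-19    1.186e-18
        slow vs fast   -1.3321 1.348e-18    8.090e-18
      normal vs fast   -0.3169 1.976e-12    1.185e-11
```

Cohort means (same run): `w_total` rises from −0.05 (SD 0.01) at very slow
speed through 0.06 and 0.16 to 0.36 (SD 0.05) N m rad kg⁻¹ at fast speed —
the loop flips from clockwise (net absorption, passive spring–damper
behaviour) to counter-clockwise (net generation, active push-off) as walking
speed increases — and peak power climbs from 2.6 to 7.6 W kg⁻¹.

File-based workflows are available through `run_simulate()`, `run_analyze()`,
`run_summarize()` / `run_pipeline()`, or the command-line wrapper
`inst/cli/ankleloop.R` (`simulate`, `analyze`, `summarize`, `all`
subcommands).

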