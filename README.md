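# emdtrigger

Simulation and analysis of closed-loop experiments in which a tethered
actuator assists or perturbs rapid arm extension **within the
electromechanical delay** — the ~40 ms lag between the onset of muscle
electrical activation and the onset of contraction. Because a fast enough
EMG-triggered pull starts moving the arm before the muscle itself does,
this manipulation can probe how precisely timed mechanical sensation
interacts with voluntary activation, a question relevant to robotic
rehabilitation for neurological disease.

The package is aimed at motor-control and rehabilitation-robotics
researchers who want a fully testable, download-free model of this
paradigm: every stage from the real-time trigger to the mixed-model
contrast table runs on synthetic cohorts whose condition effects are known
generator truths.

## What it implements

* **Protocol** — the six conditions (control; rapid/delayed assistance,
  0.31 s pulls; rapid/delayed perturbation, 0.10 s opposing pulls; passive)
  with 50-trial blocks (10 unpulled / 30 pulled / 10 unpulled), randomized
  block order with passive last, cue intervals uniform on 5–15 s, and
  40 rad/s pull commands.
* **Real-time onset detection** — threshold set 1% above the previous
  rest period's maximum squared EMG sample; the trigger is the first
  post-cue sample whose square exceeds it:

  `threshold = 1.01 * max(x_rest^2)`, `onset = min{ i >= cue : x_i^2 > threshold }`

* **Synthetic cohorts** — per-trial agonist/antagonist surface EMG
  (rest noise + burst-modulated noise with envelope
  `(t/tau) e^(1 - t/tau) A`), reaction times ~ N(180, 25) ms, the detector
  run in closed loop to launch pulls, and wrist/elbow markers at 200 Hz
  synthesized from the integrated arm angle.
* **Signal pipeline** — rectification, zero-phase 4th-order Butterworth
  high-pass (20 Hz) then low-pass (10 Hz); activation peaks within 200 ms
  of the detected onset, normalized per participant to the control-block
  mean; signed peak arm angular velocity from the planar
  wrist-about-elbow angle; reaction time = cue-to-onset.
* **Statistics** — per outcome, a linear mixed model on trial-level data
  (`value ~ condition + order + (1 | participant)`, ML), a 4-df
  likelihood-ratio test for the condition effect, and all 10 pairwise
  condition contrasts from estimated marginal means with Bonferroni–Holm
  adjustment and percent differences `(EMM_A - EMM_B)/EMM_B * 100`.

## Worked example

```r
library(emdtrigger)

params  <- generator_params(n_participants = 14, seed = 101)
metrics <- simulate_metrics(params)          # pulled-phase trials, tidy table
results <- analyze_outcomes(metrics)
get_contrast(results, "agonist", "rapid_assist", "control")[
  , c("estimate", "SE", "holm_p", "percent_difference")]
```

```
  estimate       SE       holm_p percent_difference
1 62.91026 3.673433 7.631015e-65           62.82013
```

The rapid-assistance condition's agonist activation is estimated 62.8%
above control (the estimate is the difference of estimated marginal means
on the normalized scale, where control sits at ~100%), with a Holm-adjusted
p-value of 8e-65 at this trial count. The generator truth is +68.97%; the
shortfall is the documented attenuation of peak-ratio recovery at the
latency-calibrated burst amplitude (see the methods vignette, *Known
limitations*).

```r
print(results)
#> Outcome: agonist
#>   condition LRT: chi2(4) = 577.15, p = 1.367e-123 (n = 14 participants)
#>   control vs rapid_assist: -38.6% (Holm p = 7.631e-65)
#>   control vs delayed_perturb: -44.5% (Holm p = 4.735e-107)
#>   ...
#> Outcome: antagonist
#>   condition LRT: chi2(4) = 781.97, p = 6.165e-168 (n = 14 participants)
#>   ...
```

A disk-based run (`run_pipeline(run_config(seed = 1), "out/")`) writes the
dataset, per-trial `metrics.csv`, `models.csv`, `contrasts.csv`, a
condition-mean `summary.csv`, and a plain-text report. A thin CLI wrapper
is installed at `inst/cli/emdtrigger`
(`emdtrigger pipeline --config cfg.yaml --seed 1 --out DIR`).

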