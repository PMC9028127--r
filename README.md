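# spiroqc

Automated quality assurance for forced expiratory spirometry maneuvers.

Spirometry is effort-dependent: FEV1 and FVC are only reportable when the
maneuver behind them was performed correctly, and judging that requires
both quantitative rules and a trained eye on the flow–volume and
volume–time curves. `spiroqc` implements the whole quality-assurance
chain as deterministic, inspectable R code, for engineers and
researchers building or validating spirometry QC systems:

* **Indices** — back-extrapolated time zero t₀ (steepest tangent of the
  volume–time curve extended to V = 0) and BEV; FEV1 = V(t₀ + 1 s) −
  V(t₀); FVC; PEF and tPEF; FET; end-of-forced-expiration (EOFE) via
  volume plateau (≤ 0.025 L change over the final second), FET ≥ 15 s,
  or session-level FVC repeatability (≤ 0.150 L from the best FVC).
* **Artifact detection with localization** — deterministic signal-domain
  detectors for cough, glottic closure, flutter (obstructed mouthpiece /
  device fault), early termination, extra breath, hesitant start and
  variable flow, each returning a time interval, the volume at onset and
  a score in [0, 1]. All thresholds are named config keys
  (`?spiro_config`).
* **Acceptability, usability, grading, messages** — a decision table
  (shipped as data) combines rule checks and findings into per-maneuver
  FEV1/FVC acceptability and usability, session grades A–F/U per index
  from counts of acceptable maneuvers and repeatability tiers
  (0.150/0.200/0.250 L adult; 0.100/0.150/0.200 L at age ≤ 6), operator
  warnings and patient guidance.
* **A simulator with ground truth** — a two-phase closed-form maneuver
  template (linear rise to PEF, scaled exponential decay) with
  kind-specific artifact injectors and seeded, hash-substreamed
  randomness, so every rule and detector can be tested end to end with
  known labels and no patient data.
* **Evaluation statistics** — confusion-matrix metrics (sensitivity,
  specificity, PPV, NPV, balanced accuracy = (sens + spec)/2),
  exact-match grade accuracy, and chi-squared homogeneity tests of
  per-group quality proportions.

## Worked example

Simulate a three-maneuver session in which the third maneuver carries a
45% cough spike at 0.5 s, then run the full pipeline:

```r
library(spiroqc)

g <- generate_session(list(
  maneuver_spec(fvc_true = 4.00, seed = 1),
  maneuver_spec(fvc_true = 3.97, seed = 2),
  maneuver_spec(fvc_true = 4.02, seed = 3,
                artifacts = list(artifact_spec("cough", onset = 0.5,
                                               magnitude = 0.45)))),
  session_id = "demo")

report <- assess_session(g$session)
report$indices[[1]]
#> <spiro_indices m1: FEV1=3.468 L, FVC=3.959 L, PEF=7.98 L/s, BEV=0.044 L,
#>  tPEF=0.03 s, FET=3.48 s, plateau=TRUE, EOFE=TRUE>
report$findings[[3]]
#>    kind t_start t_end v_at_onset score
#> 1 cough    0.38  0.74   2.296433     1
report$grade
#> <session grade: FEV1 B (delta 0.021 L, 2/2 acc/usable), FVC A (delta 0.025 L, 3/3)>
#>   ! Cough detected within the first second of expiration; FEV1 is not reportable from this maneuver.
```

Reading this: maneuver 1 is clean — plateau reached, BEV well under the
max(0.100 L, 5% FVC) limit. The injected cough is found and localized to
[0.38, 0.74] s, inside the first second after t₀, so maneuver 3's FEV1 is
neither usable nor acceptable while its FVC is unaffected. The session
keeps three acceptable FVCs within 0.025 L (grade A) but only two
acceptable FEV1s (grade B), and the operator gets the matching warning.

Proportion trends across operator groups use raw counts:

```r
monthly_quality_comparison(data.frame(
  label = c("month 0", "month 1", "month 2"),
  num = c(140, 359, 771), den = c(171, 431, 840)))
#> <trend_result>
#>   month 0    140/171 (81.9%)
#>   month 1    359/431 (83.3%)
#>   month 2    771/840 (91.8%)
#>   chi2 = 26.65 (df 2), p < .0001
```

Session files are a small JSON schema (`?read_session`); a command-line
front end is provided in `exec/spiroqc` with `assess`, `simulate` and
`evaluate` subcommands. The methods vignette
(`vignettes/spirometry-qc-methods.Rmd`) documents the models, thresholds,
numerical choices and limitations.

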