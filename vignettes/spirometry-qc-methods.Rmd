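---
title: "Quality assurance of forced expiratory maneuvers: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quality assurance of forced expiratory maneuvers: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spiroqc)
```

## The problem

Spirometry reports an effort-dependent measurement: FEV1 and FVC are only
meaningful when the forced expiratory maneuver was performed correctly.
The 2019 ATS/ERS technical standard expresses "performed correctly" as a
set of quantitative rules (back-extrapolated volume limits, an
end-of-forced-expiration requirement, repeatability tiers) plus visual
checks for artifacts a trained operator recognizes on the flow--volume
and volume--time curves: cough, glottic closure, an obstructed mouthpiece
("flutter"), early termination, an extra breath, a hesitant start.
`spiroqc` implements that whole chain as deterministic, inspectable
code: per-maneuver indices, localized artifact findings, per-index
acceptability and usability verdicts, session-level A--F/U grades, and
operator/patient messages, together with a simulator that produces
labeled maneuvers so the chain can be tested end to end without any
patient data.

The detectors are deliberately signal-domain rules, not a learned model:
they operate on the numeric series rather than on rendered curve images,
and every threshold is a config key with a documented unit and default
(see `?spiro_config`).

## Data model

A `maneuver` is one forced expiration on a uniform 0.01-s grid: time from
recording start, cumulative exhaled volume (liters), and flow (L/s,
positive during expiration). Time zero is recording start, not the
back-extrapolated start of test; the latter is derived downstream. When a
file carries only volume, flow is reconstructed by centered finite
differences; when both channels are present the recorded flow wins and
disagreement with the smoothed volume derivative beyond 0.05 L/s is
warned about, because differencing amplifies device noise. The immediate
neighborhood of peak flow is excluded from that consistency check: the
PEF cusp is a slope discontinuity that no finite-difference scheme can
reproduce, so a mismatch there carries no information.

A `session` bundles one or more maneuvers (typically three) with an
optional subject age. The on-disk schema is a small JSON document — a
vendor-neutral reconstruction of the numeric intermediate that QC systems
extract from device reports; it is not any vendor's export format. A
two-column CSV import (`time`, `volume`) covers the minimal case.

## Indices

Back-extrapolation finds the steepest smoothed slope of the volume--time
curve (5-point moving average of the centered derivative; raw 0.01-s
differencing is noise-dominated) and extends that tangent to V = 0. Its
time intercept is `t0`; the measured volume at `t0` is the
back-extrapolated volume (BEV). All timing indices are referenced to
`t0`: FEV1 is the interpolated volume at `t0` + 1 s (linear
interpolation; reported as missing when the record ends more than half a
sample earlier), FVC is the maximum exhaled volume above V(`t0`), PEF is
the maximum recorded flow after `t0`, and FET runs from `t0` to the end
of expiration.

Two different notions of "end" are used deliberately. FET ends at the
last sample with flow above a zero-flow floor (0.025 L/s), so sensor
drift at near-zero flow cannot inflate FET. The plateau windows, by
contrast, are evaluated on the full expiratory record (up to any
sustained inspiratory segment): a subject who holds the mouthpiece at
zero flow for two seconds has genuinely reached a volume plateau even
though FET ended earlier. A plateau means the volume changed by at most
0.025 L over the final 1-s window; the reported onset is the end time of
the earliest window from which all later windows comply. The
end-of-forced-expiration (EOFE) requirement is met by a plateau, by
FET >= 15 s, or — at session level — by an FVC within 0.150 L of the
session's best usable FVC.

## Artifact detectors

All fractional thresholds are relative to a local flow envelope (running
median of smoothed flow, 0.3-s window), which makes them scale-free
across subjects; each finding carries an interval on the time axis, the
volume at onset (locating it on the flow--volume curve as well), and a
surrogate score in [0, 1] (amplitude relative to threshold, mapped by
`min(1, ratio/2)` — the rule detectors have no calibrated confidence, and
any monotone surrogate serves).

* **Cough**: from a local minimum of smoothed flow, the drop from the
  preceding maximum must reach 25% of the envelope (and 0.15 L/s
  absolute — below that a dip is indistinguishable from sensor noise)
  and flow must rebound by 15% of the envelope within 0.5 s. The rebound
  requirement is what rejects ordinary exponential decay, however steep.
  Three or more qualifying dips within twice the cough window are treated
  as sustained periodicity and handed to the flutter detector; the
  periodicity count ignores the absolute-depth floor so a fading
  oscillation still reads as periodic.
* **Glottic closure**: flow falls from above 10% of PEF to below the
  zero-flow floor within 0.1 s and stays there for 0.25 s (or to the end
  of the record), with no volume plateau in the preceding second — a
  plateau before the stop means the maneuver simply finished. Brief
  noise excursions above the floor are bridged (gaps < 0.05 s).
* **Flutter**: the flow is band-pass filtered (5--15 Hz, 2nd-order
  Butterworth, forward--backward), and segments where the oscillation
  amplitude reaches 15% of the envelope for at least 0.3 s are reported.
  Segments are only evaluated where the envelope is at least 0.25 L/s;
  a relative threshold is meaningless near zero flow.
* **Early termination**: one end-of-record finding when neither a plateau
  nor a long FET satisfies EOFE and no glottic closure explains the stop.
  The session-level repeatability branch is resolved by the QC layer, so
  a finding can coexist with a passing EOFE criterion after pass two.
* **Extra breath**: smoothed flow below -0.05 L/s for at least 0.15 s
  with expiration resuming afterwards; a terminal inspiration with no
  resumption is the recording ending, not an artifact.
* **Start quality**: hesitant start when BEV exceeds
  max(0.100 L, 5% FVC); variable flow when the time to peak flow exceeds
  0.15 s without a hesitant start.

`scan_artifacts()` unions the detectors and resolves overlapping
cough/flutter findings by score.

## The decision table and grading

The acceptability/usability table ships as data
(`inst/extdata/qc_criteria.csv`, surfaced by `qc_criteria()`): criterion
id, the index it affects, whether it gates usability or only
acceptability, and the operator/patient message texts. Any failed
criterion from either the quantitative rules or the detectors fails the
affected flag (union of failures — conservative, as a QC system should
be). FEV1 is governed by the first second after `t0`: BEV within limits,
a measurable first second, no cough/closure/flutter overlapping it
(usability), and additionally no extra breath before `t0` + 1 s
(acceptability). FVC usability requires BEV within limits and an
uncorrupted volume record (no extra breath or flutter anywhere);
acceptability adds EOFE, no glottic closure, and no unexplained early
termination. Whether flutter should invalidate FEV1, FVC or both is not
settled by the standard's wording; the shipped table fails both, flagged
here as an assumption a user can correct in the CSV. Variable flow is
warning-only: it triggers a message but fails no flag.

Session grading per index follows the rating tiers: A needs >= 3
acceptable maneuvers with the two largest values within 0.150 L; B is 2
acceptable within 0.150 L; C >= 2 within 0.200 L; D >= 2 within 0.250 L;
E >= 2 beyond that or exactly one acceptable; U no acceptable but >= 1
usable; F neither. Ages <= 6 use 0.100/0.150/0.200 L. Grades A--C are
"good quality". Because the session's best FVC feeds back into EOFE, the
pipeline runs two passes: indices and findings once, then re-assessment
with each maneuver's distance to the best usable FVC. One caveat worth
stating: grading is *not* monotone in maneuver quality in full
generality — admitting an additional acceptable maneuver whose value
widens the top-two repeatability gap can lower the grade (values
4.00/3.90 grade B; adding an acceptable 4.35 makes the delta 0.35 and
the grade E). That is a property of the rating tiers themselves, not of
this implementation; the test suite asserts monotonicity on value sets
within one tier, where it genuinely holds.

Messages deduplicate by criterion id across maneuvers, are ordered by
id, and add a repeat-maneuver prompt whenever either index grades below
C. The texts are this package's own English phrasings keyed by criterion
id.

## The simulator

The physiology template is a two-phase curve chosen for having closed
forms, not for respiratory-mechanics realism: flow rises linearly to PEF
over `rise_time`, then follows dV/dt = (FVC - V)/tau scaled to be
continuous at the junction, which makes the tail exponential with
effective constant (FVC - V_rise)/PEF. Closed-form volume, FEV1 and FVC
are therefore available as oracles for every generated curve. Recording
continues until the trailing 1-s volume change falls to 0.01 L — well
under the 0.025-L plateau threshold — so clean maneuvers plateau robustly
under noise. Gaussian flow noise (default 0.02 L/s, device-quality) is
added last and volume is the exact trapezoidal integral of the final
flow, so flow--volume consistency holds by construction.

Artifacts are injected by kind-specific transforms: a cough multiplies
flow by a dip (60% of its duration) and rebound overshoot (40%); glottic
closure ramps flow to zero in 30 ms and keeps 0.5 s of zero-flow tail;
flutter adds a 10-Hz sinusoid scaled to the clean flow; an extra breath
is an inspiratory half-sine re-inhaling the stated volume followed by a
compensating expiratory bump (the subject breathes in, then finishes
exhaling); a hesitant start prepends a 0.5 L/s prefix exhaling the stated
volume, with the blast rising from the prefix flow so no artificial
discontinuity is introduced; early termination truncates the record.

Each injector has a documented "strong regime" in which its artifact is
unambiguous — e.g. cough magnitudes 0.35--0.6 with onsets drawn while
flow is still a substantial fraction of PEF (scaled by the template's
effective decay constant). A 25% dip of a 0.1 L/s flow is below sensor
noise and invisible to any detector or reviewer; the benchmark draws
onsets where the artifact is physically visible. Magnitudes near the
detection thresholds (a 0.30 dip, a 5% oscillation) are deliberately
usable for below-threshold tests.

Cohorts fan all randomness out from one master seed through stable
per-session and per-maneuver hash substreams, so a dataset is bit-for-bit
reproducible and independent of generation order. The default artifact
mix is uniform over the six injectable kinds — no claim of clinical
prevalence realism is made, and the mix is a parameter. Each flawed
session carries one artifact in one maneuver; subject-level FVC/PEF are
drawn once per session (FVC 3.0--4.5 L, PEF 1.8--2.3 x FVC, rise
0.03--0.08 s) with small per-maneuver variation.

What passing tests on this simulator do **not** show: performance on real
curves with device-specific noise spectra, BTPS drift, leaks (explicitly
out of scope), pediatric effort patterns, obstructive/restrictive loop
shapes, or artifact classes outside the six modeled kinds. The simulator
exists to exercise every rule and detector with known truth, not to
emulate a patient population.

## Evaluation statistics

`confusion_metrics()` reports sensitivity, specificity, PPV, NPV and
balanced accuracy (exactly the sensitivity/specificity mean) as percents;
zero-denominator cells are reported as missing and flagged, never as
silent zeros — with imbalanced classes a silent 0 (or 100) would
mislead. Display rounding is half-up to one decimal, matching how
clinical tables print (banker's rounding would turn 94.25 into 94.2).
`monthly_quality_comparison()` tests homogeneity of per-group proportions
with Pearson's chi-squared on the k x 2 count table, without continuity
correction — at the group sizes this is built for the correction is
immaterial, and the uncorrected statistic is the textbook default for
k > 2; p-values below 1e-4 display as "< .0001". `run_batch()` ties the
pipeline together over session files, skipping unreadable inputs with a
logged reason and, when a truth sidecar is supplied, producing per-flag
metrics and exact-match grade accuracy.

## Numerical choices, in one place

* Interpolation is linear everywhere: monotone, simple, and defensible at
  0.01-s resolution. Linear interpolation of an exponential sampled at
  h = 0.05 s carries a worst-case error of h^2/8 x max|V''| (about 8 mL
  for a 0.4-s time constant), which is the bound the resampling tests
  assert.
* The back-extrapolation slope is the maximum of a 5-point smoothed
  derivative; the smoothing localizes `t0` to about two sample intervals,
  which at the tangent slope near `t0` bounds the induced FEV1/FVC error
  within a few mL on noise-free curves (asserted in the tests).
* Repeatability deltas use the two largest values; a single value has
  delta 0 by convention.
* Ties and degenerate inputs: an all-zero volume series, a non-positive
  peak slope, or an expiration shorter than one sample are errors, not
  silent zeros; records shorter than the plateau window return "no
  plateau" rather than erroring.
* Problem sizes in the shipped tests — a 200-maneuver detector benchmark
  plus clean mates, cohorts of 12--60 three-maneuver sessions — were
  chosen so the whole suite exercises every rule, detector and grading
  path with comfortable statistical margins while staying quick to run
  on one core.

## Known limitations

Leak detection is intentionally absent. The decision table's flutter
policy is an assumption (see above). The simulator's artifact mix and
physiologic parameter ranges are stipulated, not fitted to any
population. The detectors' thresholds are defaults that a deployment
against a specific device should revisit through the config — that is
why every one of them is a named key rather than a constant in code.
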