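---
title: "Validating epoch-level posture trackers and correcting for misclassification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Validating epoch-level posture trackers and correcting for misclassification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(postureval)
```

## The problem

Consumer and research accelerometers worn at the thigh report one activity
label — sitting, standing, walking, or idle — per 30-s epoch. Sedentary-
behavior research consumes these labels as daily activity distributions, so
two questions precede any substantive use of a new tracker: how often is
each epoch label right (minute-by-minute validity), and how wrong is the
daily distribution once those errors accumulate (distribution-level
validity)? The two questions have different answers: a device can be
mediocre epoch by epoch and still produce a nearly correct daily
distribution if its errors partially cancel, and a reference device used in
free living is itself imperfect, so the distribution it detects should be
corrected before it is treated as truth.

`postureval` packages the full analysis: harmonizing heterogeneous streams
onto a common epoch grid, scoring agreement, and correcting detected
distributions through a misallocation profile.

## Epoch harmonization

Reference streams (direct observation, or inclinometer exports) arrive at
1-s resolution; trackers report 30-s epochs in UTC. The reduction rule
assigns each fully covered grid epoch the activity performed longest within
it. Ties among maximal activities are broken by fixed priority — sitting,
then standing, then walking — so 8 s sitting / 11 s standing / 11 s walking
becomes standing, and a 10/10/10 three-way tie becomes sitting. This
priority deliberately favors sedentary time in ambiguous epochs, which in
real data are rare (well under 1% of epochs) and concentrated at posture
transitions.

Three conventions fill gaps the rule itself leaves open; each is a design
choice of this package:

* **Grid origin.** Epochs lie on UTC wall-clock multiples of 30 s
  (hh:mm:00 / hh:mm:30); device timestamps are floored to that grid.
  Partially covered boundary epochs are dropped, mirroring the usual
  exclusion of late-initialization periods.
* **Idle.** The tie-break covers the three activities only. Seconds with no
  activity record ("off") yield an idle epoch only by strict majority over
  each individual activity, and idle loses every tie. Idle is never a
  legal reference label.
* **Merging.** All comparison is on merged data: an epoch registered by
  only one device is excluded (and counted in a drop report). A free-living
  day enters the analysis only with at least 5 h of matched wear time;
  exactly 5 h is retained, and the day boundary respects a configurable
  timezone offset because storage is UTC.

## Laboratory protocols and analysis windows

Three standardized sessions probe different failure modes:

* **Part 1** (distinction): six 3-min segments — sitting, standing, walking
  at 80/100/120 bpm, jogging at 140 bpm — in randomized order; only the
  middle minute of each segment is analyzed (6 min total), the first and
  last minute being transition or recovery.
* **Part 2** (transitions and natural paces): five 2-min self-paced
  segments. Variant 2a analyzes the full 10 min; variant 2b excludes a
  margin of 30 s before and after each *posture-class* change. Changes of
  walking pace (jogging included) are not posture changes — only this
  reading yields the canonical 6–8 analyzed minutes over the 120 possible
  orderings, via minutes = 10 − (number of class changes). No margin is
  applied before the first or after the last segment.
* **Part 3** (slow transitions): twelve cycles of sitting down or getting
  up in 1–3 s within a 30-s transition allotment, followed by a hold.
  Exactly the first 30-s epoch after the allotment is analyzed (6 min
  total), so over-long holds do not inflate the analyzed time.

Protocol randomization is seed-deterministic and uniform over admissible
orderings; part 3 alternates sit-down and get-up cycles because consecutive
identical transitions are physically impossible, and shuffles the pace
sequence within each transition type.

## Performance values and decompositions

Agreement is scored one-vs-rest per activity on a reference × prediction
cross-tabulation (reference rows sitting/standing/walking; prediction
columns plus idle). Idle predictions are false negatives of the reference
activity and contribute to true negatives of the other activities; they are
never a true or false positive. Sensitivity, specificity, PPR (precision)
and NPR follow the standard formulas; a zero denominator produces `NA`, an
explicit undefined marker that propagates into reports rather than being
silently dropped or coerced to 0/100. Multi-part summaries pool epoch
counts before computing percentages — never averaging percentages — and
report one decimal, rounded half away from zero.

Two decompositions localize the errors. The *misdetection* decomposition
splits each detected activity's false positives by the activity actually
performed (the columns of the cross-tab); together with the PPRs it forms
the **misallocation profile**. The *sensitivity* decomposition mirrors it
on rows, splitting each activity's misses by what was reported instead.

## The reallocation estimator

Given detected minutes $D_d$ and a profile $\{PPR_d,\; a\_As\_d\}$, the
estimated actual minutes of activity $a$ are

$$\widehat{A}_a \;=\; PPR_a D_a \;+\; \sum_{d \neq a} (1 - PPR_d)\, (a\_As\_d)\, D_d .$$

Profile entries are accepted on the printed 0–100 scale and used on the 0–1
scale internally. Each split must sum to 100% within ±0.3 percentage points
— printed profiles are rounded to one decimal and may not sum exactly (e.g.
33.3 + 66.6) — and when the sums are exact the estimator conserves total
minutes. Estimated minutes are kept unrounded internally and rounded to
integers only at report time; shares divide the *integer-rounded* minutes
by wear time, matching the convention of published minute tables (116/774
prints as 15.0%, where unrounded minutes would print 14.9%).

The estimator is scale-free: it can be applied to per-day minutes and
aggregated, or directly to mean minutes per day. Only the mean-level
application is exercised against published values here; per-day application
is available but its aggregation is a user choice.

## The synthetic-data generator

No deposited subject data is required: every stage is tested on simulated
data with known structure.

* **Truth.** Free-living days are alternating activity bouts. Durations are
  lognormal (`sdlog` 0.8) with mean bouts of 20 / 8 / 3 min for sitting /
  standing / walking — heavy-tailed sitting bouts being the stylized fact
  of SB data — and the target mix defaults to 57 / 28 / 15% of wear time
  with 774-min days, a typical adult free-living profile. Bout types follow
  a reversible three-state chain constructed so the stationary time shares
  equal the target mix exactly (feasible whenever no activity would need
  more than half of all bouts), and each day starts in the time-stationary
  state (a length-biased bout with uniform residual), which keeps windowed
  shares unbiased despite truncation at both ends. Lab sessions follow a
  protocol, with each posture change completing within at most 5 s of the
  planned boundary.
* **Devices.** Observation reduces truth to the grid, then corrupts each
  epoch through a row-stochastic confusion matrix `C[true, reported]`;
  epochs overlapping a truth change are additionally misreported with
  probability `transition_blur` (default 0.5; transitions demonstrably
  degrade sitting detection but no rate is published, so the default is a
  deliberately harsh stress setting), and
  epochs drop out with a configurable probability (0.8% reproduces the
  scale of unexplained lapses seen in practice).
* **Determinism.** Every generator draws from an isolated, seeded RNG
  stream and emits provenance (seed plus configuration digest). Identical
  seeds give bitwise-identical fixtures.

What the simulator does *not* emulate: raw tri-axial acceleration,
device-specific classifier idiosyncrasies, circadian structure within a
day, and non-wear misclassified as idle. Passing tests therefore certify
the analysis logic — harmonization, scoring, reallocation — not any claim
about a physical device.

## Numerical conventions and problem sizes

* Reporting rounds half away from zero to one decimal (integer minutes for
  minute tables). Undefined values stay `NA` end to end.
* Statistical tests in the suite run at fixed seeds with pre-stated
  tolerances: confusion-matrix convergence and implied-performance
  agreement are checked on ~10,000 epochs at ±2 percentage points; the
  end-to-end recovery of truth shares from a simulated sub-study profile is
  checked on 20 simulated days of sub-study and 20 of free living (~31,000
  merged epochs each) at ±1.5 points. At single-day scale the recovery is
  necessarily weaker because the profile depends on the truth mix, which
  fluctuates by several points between individual days — a real limitation
  of mix-dependent misallocation profiles, visible in the simulator.
* The free-living mix check pools 100 simulated days at ±2 points.

## Known limitations

* The misallocation profile conflates device error with the activity mix
  of the sample it was estimated on; transporting a profile to a population
  with a very different mix biases the correction.
* No uncertainty is propagated through the reallocation; the estimator
  returns point values.
* The wear-time filter counts registered epochs only; it does not attempt
  proprietary non-wear detection.
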