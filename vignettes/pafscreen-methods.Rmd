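---
title: "Rhythm-based PAF screening: model, parameters and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rhythm-based PAF screening: model, parameters and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pafscreen)
```

## The detection problem

Paroxysmal atrial fibrillation (PAF) appears in long-term ECG as episodes of
highly irregular ventricular response: the RR interval sequence loses its
short-range structure. A screen that flags local RR irregularity finds these
episodes cheaply, but premature beats (PACs/PVCs) produce the same local
signature — a short coupling interval followed by a compensatory pause — and
are common in exactly the patients monitored for PAF. `pafscreen` implements
a beat-wise rule-based detector with an explicit premature-beat rejection
stage, so that isolated ectopy, frequent ectopy, bigeminy and trigeminy do
not surface as false AF episodes.

## The rhythm-change statistic

For each QRS (beat) $i$ the statistic

$$R_c(i) = \frac{\operatorname{sd}(RR_i,\ldots,RR_{i+5})}{\operatorname{mean}(RR_i,\ldots,RR_{i+5})}$$

is the coefficient of variation of the six intervals following the beat
(population-form sd by default; `std_mode = "sample"` is available). It is
dimensionless and scale invariant, so bradycardia or tachycardia do not move
it. Beats with $R_c$ strictly above a threshold are flagged; maximal flagged
runs (merged across gaps shorter than `merge_gap_beats = 6`, one window
span) become candidate AF segments.

### Threshold calibration

A 6-interval window estimates the local CV with large sampling error: under
an i.i.d. normal model the window variance is roughly a $\chi^2_5$ draw, so
an AF segment with true CV 0.20 produces individual windows below 0.10
about 9% of the time, while sinus windows with CV 0.03 essentially never
reach 0.10. The usable operating point therefore sits well *below* the
midpoint of the two regime CVs. `calibrate_rc_threshold()` simulates both
regimes with the package generator and minimises the sum of the NSR
false-flag and AF miss rates. With the default regimes (NSR CV 0.03, AF CV
0.20, 0.8 s base RR) the error profile is flat across roughly 0.045--0.055
— simulation noise decides which grid point inside the region is reported —
and the package default **0.05** is the centre of that region. The
threshold remains a single config value (`paf_config(threshold = )`) so it
can be re-calibrated for data with different variability regimes. The
choice within the flat region trades the screen's false-flag rate on sinus
windows (which stretches detected boundaries when a stray flag merges into
an episode's run) against the rechecks' false-rejection rate on AF
segments (which rises with the threshold, since a quiet re-screen becomes
easier to satisfy); 0.05 keeps the AF false-rejection of the cascade at
about 3% at the cost of a rare (about 1% of episodes) boundary
overshoot of 7--8 beats.

## The rejection cascade

Candidates pass through three tests; a candidate is AF only if none fires.

**Single premature beat.** One ectopic pair (coupling + pause) perturbs
exactly 7 consecutive windows — the window must contain one of the two
perturbed intervals, and a 6-window slides over them seven times. Candidates
whose longest continuous flagged run is 10 beats or fewer are rejected; the
bound is strict ("exceeds 10"), so a run of 11 survives.

**Clustering.** Surviving candidates have their intervals clustered by
K-medoids (k = 3) on two features per interval: the interval itself (s) and
the ratio of its first difference to the interval (dimensionless). Coupling
intervals, pauses and normal intervals occupy distinct regions of this
plane; AF intervals form one diffuse cloud. Features are used in their
natural units. We examined per-segment z-scoring and rejected it as the
default: the two features are strongly correlated under AF (about 0.7), and
equalising their scales makes the partition split along interval *value*,
producing artificially uniform bands that defeat the downstream rechecks;
in natural units the difference-ratio feature dominates and AF groups keep
broad, overlapping RR ranges with nearly equal means — the behaviour the
rechecks rely on.

The medoid search is exhaustive (all $\binom{n}{3}$ triples) for segments of
up to 14 intervals, where it is cheap and certifiably optimal, and a
deterministic PAM-style greedy build plus best-improvement swap phase for
longer segments. The seed only breaks ties; results are reproducible.

**Fine-tuning.** A single refinement sweep follows: each interval may move
to the group of its *second-nearest* medoid when that strictly lowers the
pooled within-group sum of squares of the raw RR values (groups never drop
below two members). Two formalisation choices matter here and were made
deliberately:

* The objective is the *size-weighted* (pooled) within-group spread. An
  unweighted sum of per-group standard deviations can be reduced by pouring
  normal intervals into a contaminated group — dilution shrinks that
  group's sd while the partition degrades — and greedy descent exploits
  exactly that loophole, draining the normal group until the cascade
  misfires. The pooled form cannot be gamed this way.
* One sweep, not descent to convergence, and only moves to the
  second-nearest medoid. The sweep's purpose is to correct the handful of
  boundary misassignments K-medoids makes on structured rhythms (the
  post-pause normal interval of trigeminy looks locally like a coupling);
  iterating to a fixed point instead re-sorts diffuse AF segments into
  interval-value bands, which manufactures premature-beat structure where
  none exists. A single restricted sweep cleans the structured rhythms
  (trigeminy grouping becomes exact) while leaving AF partitions diffuse.

**Bigeminy/trigeminy recheck.** A geminal pattern is declared when some
window of 6 consecutive intervals holds equally many longest-group and
shortest-group members, each at least `geminy_min_count`. The default is 3
— the strict reading of "more than two", which a bigeminy window (3 short +
3 long) satisfies. A trigeminy window holds 2 + 2 and does not satisfy the
strict count; we examined the permissive reading (`min_count = 2`) and
found it fires on about three quarters of AF segments (balanced counts of
the extreme groups arise by chance in a diffuse cloud), so the package
keeps the strict default and lets trigeminy fall through to the
frequent-ectopy recheck, which eliminates it reliably (its near-median
group is the uniform normal intervals). When the pattern is present, the
longest-interval group is re-screened: geminal pauses are nearly uniform,
so every recheck window falls at or below threshold and the candidate is
rejected.

**Frequent-ectopy (multi-PB) recheck.** Otherwise the group whose mean lies
closest to the segment's median interval — with frequent ectopy, the normal
beats, which remain the majority — is re-screened in temporal order. A
quiet recheck rejects the candidate. Selections shorter than one window
(fewer than 6 intervals) do not reject by default: every premature-beat
rhythm the cascade targets leaves a large selected group (20+ normals out
of 30 for frequent ectopy, 10+ pauses for geminal rhythms), whereas tiny
selected groups arise from chance splits of AF clouds; treating them as
"quiet" would convert about 5% of AF segments into false rejections. The
spec-style alternative is available as `recheck_rc(short = "reject")`.

**Detection closure.** An $R_c$ value at beat $i$ describes intervals
$i..i+5$, so a flagged run $[s, e)$ is evidence of irregularity inside
beats $s..e+5$. Boundary windows flag while only partially overlapping the
episode, which biases a one-sided closure: assigning the whole 6-beat span
to the offset places the detected end about 4 beats late on average.
`detect_paf()` splits the span symmetrically (+3 beats at each edge), which
centres detections on the true episode and keeps both boundary errors
within a few beats.

## The synthetic generator

The generator provides the study conditions for every test:

* **NSR**: AR(1) around `base_rr = 0.8` s with coefficient 0.5 and marginal
  CV `nsr_cv = 0.03` — mild short-range correlation, below-threshold
  irregularity.
* **AF**: i.i.d. normal with CV `af_cv = 0.20`, truncated to [0.2, 2.5] s.
  The i.i.d. unimodal draw guarantees the no-cluster-structure property the
  rejection stage assumes of AF.
* **Ectopy**: a premature beat contributes a coupling interval
  (`coupling_fraction = 0.6` of the local 6-interval mean) and a pause
  (`compensatory_fraction = 1.4`), rate-adaptive like real ectopy. Single
  PB, `n_pb` irregularly spaced PBs (spacing at least 3 beats), strict
  alternation (bigeminy) and short/long/normal cycling (trigeminy) are
  built from the same primitives.
* **Recordings** concatenate labelled episodes; the joining interval is the
  next episode's base RR, so ground-truth boundaries are exact.
* **Waveforms** (`render_ecg()`) place a Gaussian-windowed biphasic
  template (width about 80 ms, absolute maximum at its centre) at
  cumulative RR times, plus optional 0.3 Hz baseline wander and white
  noise, and return the true QRS sample indices.

What the generator does *not* emulate: P/T/f-wave morphology, respiratory
sinus arrhythmia beyond AR(1), heavy-tailed AF interval distributions,
rate drift, or noise bursts correlated with movement. Passing tests
therefore demonstrate the internal logic of the screen and cascade under
the stated statistical regimes, not clinical performance on Holter data —
for that the WFDB reader accepts the public MIT-BIH arrhythmia and atrial
fibrillation databases, which users can download themselves.

## Numerical and degenerate-input choices

* Windows are anchored on their left beat; flags use strict `>`, rechecks
  use `<=`.
* Population-form sd in $R_c$ (divide by 6); `sample` mode divides by 5.
* Intervals are truncated to [0.2, 2.5] s at generation; `rc_series()`
  refuses non-positive intervals and returns `NA` where fewer than six
  contiguous intervals follow a beat. Quality gating marks intervals
  non-contiguous across dropped beats so no window straddles a gap.
* Clustering of fewer than 3 distinct feature points returns a degenerate
  partition grouped by value; the cascade then skips the geminal test if
  only one group exists.
* Ties in medoid search resolve to the lexicographically first optimum;
  ties in median-group selection go to the larger, then lower-id group.

## Problem sizes used by the test-suite simulations

Property-style checks run on 31-beat segments (the premature-beat test
segment length, 30 intervals) with up to 1000 seeded replicates per
rhythm class, and on 100 seeded multi-episode recordings of about 400
beats; the clustering oracle compares against exhaustive search on up to
12 intervals. These sizes keep every invariant measurable with comfortable
statistical margins.

## Known limitations

* The screen needs six contiguous intervals; AF episodes shorter than about
  10 beats are not reliably separable from isolated ectopy by design (the
  run-length rule absorbs them).
* With only ~25 windows per 31-beat segment, the rechecks retain a few
  percent two-sided error: a couple of percent of frequent-ectopy segments
  survive and about 3% of AF segments are rejected at the calibrated
  threshold.
* The QRS detector is a plain derivative-energy detector meeting the
  package's contracts on synthetic waveforms; on poor-quality wearable
  signals the quality gate drops windows rather than rescuing them.
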