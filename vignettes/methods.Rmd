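---
title: "Methods: activation mapping, mechanism classification and the induction tally"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: activation mapping, mechanism classification and the induction tally}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`vtmap3d` implements the desk-side analysis of a canine acute-ischemia
arrhythmia experiment: multichannel intramural electrogram recordings are
turned into activation maps, each induced tachycardia complex is classified
as focal or reentrant, microelectrode traces are screened for delayed
afterdepolarizations (DADs) and triggered activity (TA), and per-animal
induction outcomes are tallied into group-level block counts with
contingency statistics. This vignette describes the models and the
decisions behind them; every empirical number quoted here is computed by
the package's own tests or acceptance script.

## Recording model

A recording session is a channels × samples matrix (mV) at 3200 Hz,
band-passed 3–1300 Hz, with user-supplied surface-QRS trigger times. The
electrode grid holds up to 23 plunge needles with up to three layers
(endo, mid, epi). Because the study hardware's needle coordinates are not
published, the default layout is a 5×5 lattice minus two corners at 8 mm
spacing (configurable; any `positions` matrix is accepted). Two sites are
*adjacent* when they share a needle or sit on needles within 1.5× the
lattice spacing — the adjacency needed by the reentry definition, which
the source material uses but never formalizes. Geodesic distances over
this graph (3-D edge lengths, layers 4 mm apart) convert conduction
velocity into activation delays.

## Synthetic electrograms: the stated world

The generator's role is to produce recordings whose ground truth is known
exactly, under the conditions the analysis claims to handle:

- **Deflection template.** Each activation contributes a biphasic
  deflection: a steep intrinsic component (~8 ms wide at its configured
  default) riding on a slower far-field base whose lobes peak near
  ±7.8 ms. Both parts are odd around the onset, so the steepest raw slope
  falls exactly at the activation time — the convention by which local
  activation is marked. The far-field lobe spacing is matched to the
  50-sample smoothing boxcar so that the smoothed derivative also peaks at
  the onset; without this, a compact wavelet's smoothed-slope maximum sits
  half a boxcar away and the ±8 ms raw refinement cannot reach back to
  the onset. This is a deliberate deviation from a plain ~8 ms
  difference-of-Gaussians template, which implementation showed to be
  incompatible with the smoothing-plus-refinement detection scheme and
  with raw max-|dV/dt| detection at the stated noise levels; real bipolar
  electrograms likewise pair a fast intrinsicoid deflection with a
  30–50 ms local complex.
- **Focal episodes** place the earliest onset at the origin; every other
  site is delayed by geodesic distance / conduction velocity (default
  0.6 mm/ms, cycle length 180 ms, entry 30 ms before QRS onset).
- **Reentrant episodes** traverse a closed, grid-adjacent circuit over
  55% of the cycle length (diastolic bridging), re-entering at the first
  circuit site each cycle, so the earliest site of every complex is
  adjacent to the latest site of the previous one. Off-circuit sites take
  the earliest arrival over all circuit sources. An optional block site
  loses >75% of its amplitude on the blocked beat and rebounds above
  baseline on the next. Defaults keep all onsets inside the −40/+80 ms
  intracardiac search window relative to the QRS onset; with a literal
  reading of the good-channel spacing clause (onset gaps ≤ 120 ms) no
  channel of a VT with cycle length > 120 ms is ever "good", so detection
  runs on the QRS-referenced path and the window constraint is what makes
  the stated recovery rates attainable.
- **VF onsets** carry a mechanism-bearing prefix of 8–40 complexes with
  cycle length shortening to 75% of nominal, followed by unlabeled
  chaotic activity (per-channel random onset trains respecting the 65 ms
  refractory bound, half amplitude).
- **Noise** is additive Gaussian, FFT-limited to the 3–1300 Hz band, with
  SD given in mV ("10% noise" = 1 mV against the nominal 10 mV
  deflection).
- **Purkinje prepotentials** are 0.5 mV Gaussian spikes of 1.5 ms width
  leading the muscle deflection by 1–11 ms (default 5), added on the
  endocardial origin and its adjacent endocardial sites.

What the generator does *not* emulate: biophysical propagation
(monodomain/bidomain), far-field QRS morphology, drifting baselines,
electrode motion, fractionated or double potentials, and microreentry
below grid resolution. A green recovery test therefore establishes that
the algorithms implement their definitions correctly — not that they
would perform identically on laboratory signals.

## Onset detection

Per beat, a preliminary raw pass establishes each channel's onsets and
per-beat peak amplitudes. A channel is *good* when all its onset gaps are
≤ 120 ms and every per-beat peak exceeds 60% of its average per-beat
maximum. Good channels and their neighbors (same or adjacent needle) are
detected raw: max |dV/dt| within ±20 ms of the peak amplitude (the window
is centered, a documented choice where the source is ambiguous). Other
channels are detected on the 50-sample boxcar-smoothed signal within the
class window — intracardiac (−40, +80) ms around the median good-channel
onset of the same needle, falling back to the QRS onset; pacing +15 to
+150 ms — then refined to the raw max |dV/dt| within ±8 ms, clamped to
the class window. VF beats are always detected raw. dV/dt is a central
finite difference; ties break to the earliest sample.

The refractory pass enforces ≥65 ms between consecutive events per
channel; violators are re-detected in the 80 ms window starting 65 ms
after the previous event and dropped (with a logged reason) when that
window holds no deflection. "Holds a deflection" is decided on the
smoothed signal: its peak-to-peak there must reach 50% of the channel's
per-beat amplitude. A raw slope floor is useless for this purpose — at
the stated noise levels single-sample noise slopes rival true deflection
slopes, while boxcar smoothing attenuates them ~7-fold.

## Mapping and sequencing

Layer-pair onsets on one needle are *consistent* when they differ by at
most ±20 ms (endo–mid, mid–epi) or ±30 ms (endo–epi), margins growing by
2 and 3 ms per following onset; margins reset at each complex (the
growth-scope is ambiguous in the source and configurable here). A layer
outside the margin of *both* other layers is re-detected within the trend
window spanned by the two in-margin layers padded by the pair margin —
subject to the same smoothed-deflection test, which is what preserves
genuinely dissociated sites (a reentrant circuit's late tail over an
early mid/epi breakthrough) instead of relocating them onto noise. VF and
paced beats are never sequenced. Isochrone bands default to the map
legend: white earlier than −25 ms, yellow −25 to 15 ms (both edges
inclusive), then 40 ms bands ending in green at the complex's latest
activation.

## Mechanism classification

For each complex after the first, using its map and its predecessor's:

- **Reentry** requires the earliest site to be grid-adjacent to the
  previous complex's latest site, supported by diastolic bridging (gap ≤
  50% of cycle length) and/or block evidence (a site at <25% of its
  typical amplitude followed by recovery). Continuous diastolic activity
  is treated as supporting, not required, evidence.
- **Focal** requires the earliest site's adjacent sites to activate after
  it, activation time to increase with distance from it (rank
  correlation > 0), and no adjacent activity later than 50% of the cycle
  length.
- The adjacency criterion takes precedence when both patterns could hold;
  a complex is never both. Cycle lengths below the layer refractory
  values (80 ms epicardium, 100 ms endocardium, midwall interpolated) are
  flagged as refractory-block candidates.

Episode typing is total: VF (changing QRS and no arterial pressure,
mechanism read from the first 8–40 complexes), sustained VT (≥10 s or
pace/shock-terminated), non-sustained VT (≥3 complexes, <10 s,
self-terminating), else not an episode. A Purkinje origin additionally
requires the prepotential on at least two endocardial channels on the
tachycardia beat *and* on atrial-paced references before and after
occlusion; the spike search scans local maxima of a high-frequency
residual (signal minus a 5 ms moving average) for 0.25–1 mV peaks no
wider than 2.5 ms at half maximum, since the muscle deflection's own
leading edge otherwise dominates the window.

## Ischemia assessment

The local interval is anchored at the max |dV/dt| within −30/+80 ms of
the QRS onset, extended forward until the tracing stays within the
isoelectric band (3× the diastolic noise SD) for 5 ms, and backward until
the local slope falls below `slope_factor` (default 0.1 — the source
names a "specific factor" without a value, so this parameter claims no
provenance) times the tracing's mean slope. A site is ischemic at a ≥45%
drop in the interval's peak-to-peak voltage from before to after
occlusion; drops in the 40–45% borderline band are confirmed by a ≥45%
drop in maximum slope. Comparisons carry an epsilon so that exactly 45%
counts, as "at least 45%" requires; the rule is monotone in post-occlusion
voltage and invariant to common gain.

## Cellular AP analysis

MDP (reported interchangeably as RMP) is the mean over 10 paced 1.5 Hz
complexes of the mean voltage in a 5 ms window ending 1 ms before the
stimulus (the window width quantifies "just before the stimulus
artifact"). APA is the phase-1 peak minus MDP; APD50/APD90 run from the
upstroke (max dV/dt) to 50%/90% repolarization. DADs are transient
depolarizations at least 1.5% of APA (~1 mV) above the diastolic baseline
*after* the last paced AP has returned to baseline; an excursion reaching
60% of APA is a triggered AP and contributes a DAD at its upstroke foot.
TA requires the upstroke to reach 60% of APA and cross the mid-upstroke
level (baseline + 55% APA, about −40 mV on a normal trace). All
thresholds are relative to the trace's own baseline and amplitude, so
counting is invariant to amplifier gain and offset — the −40 mV criterion
is deliberately implemented relative for this reason. The TA rate is
total TA across ≥4 pacing frequencies divided by the number of trials.
The generator refuses DAD latencies inside the last AP and spacings that
would merge consecutive events.

## Study tally and statistics

Each animal contributes four induction outcomes (I–II pre-drug saline,
III–IV post-treatment), each a sustained episode type with a mechanism
set (EFo/EpFo = endo/epicardial focal; R/RE = epi/endocardial reentry),
or non-sustained VT, not inducible, or not done. A mechanism *category*
(focal vs reentry) is reproducible when present at both I and II —
category-level matching is required to reproduce the published per-animal
calls (an R→RE sequence counts as reproducible reentry, yet an exact-label
rule would also misclassify animals whose focal label shifts EFo→EpFo). A
reproducible category is *blocked* when the final completed post-drug
induction shows no sustained episode containing it; non-sustained VT and
not-inducible count as absence, and a not-done final defers to the last
completed induction. These two rules, applied to the packaged tables,
reproduce every published group count (6/10, 4/9, 5/8, 1/27; focal/reentry
6&2, 2&3, 3&2; 15 treated blocks, 11 focal, 7 reentry; 11 of 16 including
the single control).

Chi-square is the Pearson statistic on the 2×2 treated/control ×
blocked/not table, 1 df, no continuity correction by default (the variant
is configurable; the source names the test but not the variant). Fisher's
exact two-tailed p sums hypergeometric probabilities ≤ the observed
table's, margins fixed, with the conventional 1e-7 relative tie guard;
tests verify it against an independent `choose()`-based enumeration
oracle to 1e-12. Note that for the OXY (4/9 vs 0/9) and BOTH (5/8 vs 1/8)
comparisons the exact test's minimum attainable p exceeds 0.05 (0.082 and
0.119); only chi-square marks those comparisons significant, which is the
test the source assigns to induction incidence.

## Numerical conventions and limitations

Times are ms relative to the surface QRS onset (negative = pre-QRS);
sample indices are 0-based in time conversions; all argmax operations
break ties to the earliest sample. Detection windows clamp to the record;
out-of-window channels are flagged missing rather than erroring.
Simulations are bit-reproducible for a given seed and argument set.

Known limitations: grid-resolution mechanisms only (no microreentry); the
VF chaos segment is unlabeled filler, not a wavelet model; the Purkinje
detector is tuned to the generator's spike morphology and the published
amplitude/width/lead bands, not to clinical Purkinje potential variety;
the in-vitro group means (AP amplitudes, TA counts under drug) are
measured laboratory quantities and are not reproduced computationally.
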