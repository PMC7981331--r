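---
title: "Methods: EEG vigilance staging and arousal-based stratification of fatigue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EEG vigilance staging and arousal-based stratification of fatigue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(arousalstrat)
```

## The scientific problem

Fatigue in major depressive disorder is clinically heterogeneous. One
proposed axis of heterogeneity is brain arousal regulation: some
fatigued patients hold a stable, even hyperstable, arousal level during
quiet rest, while others decline rapidly toward drowsiness and sleep
onset. `arousalstrat` implements an objective, EEG-based operationalisation
of this axis: a 15-minute eyes-closed resting EEG is cut into 1-second
segments, each segment is labelled with one of seven vigilance stages,
the whole recording is condensed into an *arousal stability score*
(1–11), and subjects with score ≤ 6 are assigned to a *hypoaroused*
fatigue group (score ≥ 7: *non-hypoaroused*). Questionnaire scores
(MFI-20, BDI-II, ESS, SSS, SF-A/R) are then compared between groups
with a nonparametric battery.

## Vigilance stages and the per-segment classifier

Each artifact-free 1-s segment receives one stage, ordered from high
arousal to sleep onset, with a fixed stage score (7 high … 1 low):

| Stage | Score | EEG characteristic |
|-------|-------|--------------------|
| 0     | 7     | low-amplitude, predominantly beta (12–25 Hz), no horizontal SEM |
| A1    | 6     | alpha (8–12 Hz) dominant over occipital regions |
| A2    | 5     | alpha dominant over parietal regions |
| A3    | 4     | alpha dominant over frontal regions |
| B1    | 3     | low-amplitude beta **with** horizontal slow eye movements |
| B2/3  | 2     | predominantly delta (2–4 Hz) / theta (4–7 Hz) |
| C     | 1     | K-complexes or sleep spindles |

The classifier (`classify_segment()`) applies these criteria in a fixed
decision order: graphoelements force C; otherwise dominant slow-wave
activity without alpha gives B2/3; otherwise sufficient alpha gives an
A stage sub-staged by the alpha-maximal region (ties resolved
occipital > parietal > frontal); otherwise a slow eye movement gives
B1; otherwise stage 0.

**Feature extraction.** Band powers come from a Hann-tapered
periodogram at 1 Hz resolution (1-s segments), bands summed over bins
whose centre lies in [lo, hi) and normalised by the window's equivalent
noise bandwidth, so a pure sinusoid of amplitude A contributes ≈ A²/2
µV². Relative alpha is alpha/(delta+theta+alpha+beta) averaged over the
alpha-maximal region of interest; relative slow wave is
(delta+theta)/total averaged over all EEG channels.

**Numeric thresholds are this package's calibrated choices.** The
reference vigilance-staging algorithm keeps its exact thresholds in an
external manual; we chose relative (scale-invariant) criteria —
`alpha_rel_min = 0.40`, `slowwave_rel_min = 0.55` — calibrated once so
that the synthetic generator round-trips at ≥ 90 % per-segment
agreement, and exposed every threshold in `classifier_config()`.
Relative thresholding makes the spectral staging invariant to a global
amplitude rescaling of a segment (property-tested); an adaptive
absolute-amplitude scheme would be the main alternative.

**Event detectors.** Slow eye movements: the horizontal EOG derivation
(left minus right canthus; the electrode labels are not standardised,
so role inference from labels is configurable) is band-passed 0.1–1 Hz;
a SEM is a monotone deflection ≥ 25 µV lasting ≥ 0.5 s. Sleep
spindles: the 11–16 Hz Hilbert envelope on any fronto-central channel
must exceed 3 × that channel's median envelope *and* an absolute 15 µV
floor for ≥ 0.5 s — the floor guards against the degenerate case where
a recording carries almost no sigma-band background and the median
collapses. K-complexes: a biphasic 0.5–4 Hz deflection with
peak-to-peak ≥ 100 µV whose duration (twice the extremum separation,
for the roughly symmetric shape) falls within 0.5–1.5 s.

## Preprocessing

EEG channels are zero-phase (forward–backward Butterworth) filtered
0.5–70 Hz with a 50 ± 2 Hz notch and re-referenced to the common
average; zero-phase filtering avoids phase shifts at stage boundaries.
EOG channels deliberately receive a lower 0.1 Hz high-pass: a 0.5 Hz
corner would remove the < 1 Hz slow eye movements the B1/0 distinction
depends on. Visual artifact rejection and ICA are replaced by a
deterministic surrogate: any 1-s segment in which any EEG channel
exceeds 100 µV peak is masked, and a recording with more than 15 %
masked segments is unusable (the boundary case, exactly 15 %, is kept,
matching the strict "more than" exclusion rule). The 15 % rule is
counted over 1-s segments; whether the original criterion counted
longer stretches is unstated, so per-segment counting is the
documented choice.

## The arousal stability score

`stability_score()` divides the recording into three 5-min blocks by
original segment timing and evaluates, in ascending score order with
first-match-wins:

1–3: a C stage occurred; the earliest C-containing block fixes the
score (block 1 → 1, block 2 → 2, block 3 → 3). 4–6: ≥ 1/3 of a
block's segments are B2/3, earliest block first. 7–9: the same rule
for B1. 11: ≥ 2/3 of all segments are {0, A1}. 10: ≥ 2/3 are
{0, A1, A2, A3}.

Three interpretive decisions were genuinely open and are made
explicitly here. (a) *Precedence*: the published criteria table lists
rows but no evaluation order; ascending-by-score evaluation makes
C-presence and early slow-wave blocks dominate, which is the only
ordering consistent with a published example trajectory that reaches C
and scores 3 despite extensive B2/3. (b) *The garbled final rows* of
the criteria table are read as "earliest C block determines 1/2/3".
(c) *Fallback*: scattered sub-threshold B stages can leave no row
satisfied; we return a configurable fallback of 10 (absence of any
sustained decline evidence is the non-hypoaroused regime) and flag it
in `matched_criterion`. Fractions are compared with exact integer
arithmetic (`3 * count >= n`, not floating point), artifact segments
are excluded from numerators and denominators, and "all segments" in
rows 10/11 means all non-artifact segments. An independently coded
brute-force transcription of the criteria table agrees with the
implementation on 10,000 random sequences in the test suite.

Stratification: score ≤ 6 → hypoaroused, ≥ 7 → non-hypoaroused.

## Questionnaire scoring

MFI-20: the standard item key (general 1,5,12,16; physical 2,8,14,20;
reduced activity 3,6,10,17; reduced motivation 4,9,15,18; mental
7,11,13,19; reversed 2,5,9,10,13,14,16,17,18,19) ships as
configurable data because the source publication does not print it.
Reversed items are recoded 6 − value; dimensions are 4-item sums
(4–20). BDI-II: 21 items 0–3 (items 16/18 collapse the graded options
1a/1b → 1 etc.), total 0–63. ESS: 8 items 0–3, total 0–24, with a
strict "> 10" excessive-sleepiness flag. SSS: single 1–7 rating.
SF-A/R: sleep quality as the mean of the 5-point quality items and
time in bed from bed/rise clock times with midnight wrap.

An instrument with more than 2 missing items is not scored (the
subject is excluded with a machine-readable reason); with 1–2 missing
items we impute the rounded person mean within the scale (within the
dimension for the MFI) — the admissibility rule is prescribed, the
imputation is our deterministic choice of the standard practice. The
fatigue inclusion rule keeps subjects whose general-fatigue score
*strictly exceeds* the sex- and age-band 75th percentile of a
population norm table. The shipped norm table
(`inst/extdata/mfi_norms_synthetic.csv`) is a clearly-labelled
synthetic placeholder — the real German population norms are not
reproducible from the source — so substantive use requires supplying
real norms; age-band boundaries are likewise configuration.

## Statistical battery

Group comparisons use the Mann–Whitney U test with the tie-corrected
normal approximation and *no* continuity correction, matching
SPSS-style asymptotic Z reporting; Z is signed so that a lower mean
rank in the first-listed (non-hypoaroused) group gives negative Z. The
effect size is η² = Z²/N (the rank-biserial-r² convention; Z²/(N−1) is
available), with a 90 % percentile-bootstrap CI over 10,000
replicates, groups resampled independently with preserved sizes
(percentile rather than BCa: simplest defensible choice, and
bit-reproducible under a seed). Categorical margins use Pearson
chi-square without continuity correction. Associations use Spearman
correlation (average ranks, t-approximation p), and "partial Spearman"
is realised as partial Pearson on ranks via residualisation, with
t-distribution p on n − 2 − k degrees of freedom — the standard
construction when only "partial correlation" is specified. No
multiple-testing correction is applied, mirroring the analysis plan
being reproduced.

A caveat the test suite documents explicitly: the asymptotic
(no-continuity-correction) p can differ from the exact-enumeration p
by more than 0.03 at very small samples — the worst case over all
n₁, n₂ ≤ 8 is ≈ 0.68 (at n₁ = n₂ = 1) and still ≈ 0.046 at
n₁ = n₂ = 8. The discrepancy shrinks monotonically with sample size
and is irrelevant at the cohort sizes analysed here (78/24), but exact
agreement to 0.03 at such n is unattainable without a continuity
correction, which the reproduced reporting convention excludes.

## Synthetic data: what it emulates and what it does not

`make_stage_script()` generates per-second ground-truth trajectories
(`stable_high`, `declining`, `fluctuating`, `custom`);
`synthesize_recording()` renders them into a 31-channel extended 10–20
EEG (plus 4 EOG channels) at 256 Hz by default (1 kHz supported): per
stage, band-limited noise or a 10 Hz alpha rhythm with a 2:1 regional
amplitude gradient on a pink-noise floor, 0.25 Hz / 60 µV horizontal
EOG drifts for B1, 2–6 Hz activity for B2/3, and one graphoelement per
C second (alternating a 13 Hz, 0.8-s spindle with 0.1-s cosine ramps
and a 1-s biphasic K-complex confined to fronto-central channels so
the common average does not cancel it). Oscillation phase is
continuous within a stage run. The defaults were fixed once against
the classifier's calibration contract (≥ 90 % per-segment round-trip
agreement on clean recordings; stability-score recovery exact in
≥ 80 % of recordings and within ±1 otherwise).

`generate_cohort()` draws per-subject scale totals from truncated
normals at the two groups' published means/SDs (78 non-hypoaroused /
24 hypoaroused by default; e.g. ESS 8.3 ± 4.0 vs 10.4 ± 4.0, BDI-II
29.2 ± 8.8 vs 30.3 ± 7.9), rounds and clips to the instrument range,
and back-fills item responses uniformly under the total.

What the generators do **not** emulate — and hence what passing tests
do not show about real data: no biophysical head model or volume
conduction; no realistic inter-item correlation structure within
questionnaires (items are exchangeable given the total, so item-level
analyses are exercised but not realistic); no correlation between the
EEG-derived stability score and questionnaire content beyond the group
labels (so the partial-correlation analysis runs but its population
value is near zero by construction); no medication effects on EEG; no
ocular/muscle artifact morphology beyond amplitude transients.
Truncation and rounding shift configured means slightly (≲ 0.1 on the
ESS at its defaults), which the calibration tests bound.

## Problem sizes and numerical choices

The test suite and the acceptance script run at desk scale as the
package's own choice of problem size: single-stage calibration
recordings of 60 s, mixed-profile round-trips of 300 s, a 12-recording
end-to-end score-recovery study at the full 900 s, 10,000 random
sequences for the oracle comparison, 100 replicate cohorts for the
expected group statistics, and 1,000–10,000 bootstrap replicates.
Degenerate inputs are defined, not crashed on: identical samples give
Z = 0, p = 1; constant bootstrap data gives a zero-width interval;
classification without horizontal EOG degrades to a documented mode
mapping both 0 and B1 to "0" with a warning; an all-artifact recording
is a validation error. All RNG consumption is seed-scoped: generators
and the bootstrap save and restore the caller's RNG state, evaluating
their seed argument before the state capture (lazy evaluation
otherwise rewinds a seed drawn from the global stream).

## Known limitations

The classifier approximates the reference algorithm's
anterior–posterior alpha centre-of-gravity by an argmax over three
fixed regions; B2 and B3 stay merged; no sleep staging beyond onset.
The artifact surrogate cannot remove in-band ocular or muscle
contamination the way ICA plus visual inspection would. The stability
score's precedence and fallback are configurable interpretations, not
ground truth. Real-data use requires real MFI norms and, ideally,
site-specific classifier threshold calibration.
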