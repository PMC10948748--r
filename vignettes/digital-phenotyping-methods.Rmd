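---
title: "Methods: multimodal digital phenotyping of depression"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal digital phenotyping of depression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(digimood)
```

# Scope and design

`digimood` implements the analysis layer of a week-long multimodal
assessment of depression: wrist actigraphy at one-minute epochs plus
app-derived facial, speech, language and mood-diary streams, compared
between diagnostic groups and fused into cross-validated classifiers.
The package deliberately starts *after* signal extraction: facial
action-unit (AU) presence tables, voicing/F0/intensity frame tracks and
segmented transcript tokens are inputs, not raw video or audio. Because
clinical cohorts of this kind are not publicly released, the package
ships a synthetic-cohort generator whose group presets encode the
direction and approximate size of published case-control contrasts, so
every downstream stage can be exercised, calibrated and tested end to
end.

# Actigraphy processing

## Mobility and activity summaries

An epoch is *mobile* when it records at least 4 counts/min and the
device was worn; `%mobile` is the percentage of valid (worn) epochs that
are mobile, and `cpm` the mean counts per minute. Both are reported over
three scopes: the whole week, the active period, and the nightly rest
interval. Off-wrist epochs are removed from every numerator and
denominator.

## Rest-interval detection

The proprietary software used in clinical practice detects the nightly
"major rest interval" with an unpublished algorithm, so `digimood` uses
a transparent analogue: per complete noon-to-noon day (noon boundaries
avoid splitting nocturnal sleep), the longest block in which the centred
11-epoch rolling median of counts falls below 0.2 times that day's
median count, requiring at least 240 min. Brief above-threshold
interruptions up to 20 min — nocturnal arousals — are bridged rather
than allowed to split the night; without bridging, chance clusters of
arousal epochs truncate detected rest by tens of minutes. All four
parameters are arguments of `detect_rest_intervals()`, and manually
annotated intervals bypass detection entirely.

## Sleep scoring

Within a rest interval, each epoch receives the classical weighted
activity score

$$D_i = 0.04\,c_{i-2} + 0.2\,c_{i-1} + c_i + 0.2\,c_{i+1} + 0.04\,c_{i+2},$$

and is scored sleep when $D_i < 40$ (the published medium-sensitivity
threshold; configurable). Sleep onset is the start of the first run of
at least 10 consecutive sleep epochs, offset the end of the last such
run. Sleep efficiency divides sleep duration by the rest-interval
duration (a time-in-bed analogue — the clinical software's denominator
is undocumented, so this choice is made explicit here). The sleep
midpoint is the clock time halfway between onset and offset.

Night-to-night intra-individual variability (IIV) is the *sample SD*
across nights, with two conventions worth noting. Durations are
rescaled from minutes to fractions of a day before the SD, making the
duration IIV unitless. Midpoints are circular: they are unwrapped
around the subject's circular mean midpoint before the SD, so a
subject sleeping alternately at 23:30 and 00:30 has IIV 0.71 h, not
~16 h. Alternative IIV definitions (successive-difference SDs,
normalised indices) exist; the sample SD was chosen and isolated in
`sleep_iiv()` so the convention can be swapped in one place.

# Circadian rhythm analysis

## Cosinor

`fit_cosinor()` fits $y(t) = M + A\cos(2\pi (t - \varphi)/24)$ by
ordinary least squares on the linearised design
$[1, \cos \omega t, \sin \omega t]$: $M$ is the MESOR (rhythm mean
level), $A$ the magnitude (peak minus MESOR), $\varphi$ the acrophase
(clock time of peak activity). A flat series has magnitude 0 and the
acrophase is reported as 0 with an explicit `acrophase_defined = FALSE`
flag rather than an arbitrary angle.

A whole-week cosinor fitted to rest-gated data is *not* an unbiased
estimator of the generating rhythm: suppressing counts during a rest
window that is offset from the cosine trough pulls the fitted MESOR
down, inflates the magnitude and shifts the acrophase by some tenths of
an hour. This is a property of the measurement model (the same applies
to human data), so parameter-recovery tests use rest-free simulated
rhythms, while group *contrasts* on full simulations remain meaningful
because both arms carry a similar gating bias.

## Nonparametric measures

With the series averaged into bins (60 min by default, the classical
convention; configurable because the resolution used by published
analyses is often unreported):

* **IS** (interdaily stability)
  $= N \sum_h (\bar x_h - \bar x)^2 \big/ p \sum_i (x_i - \bar x)^2$,
  1 for a perfectly day-stable pattern, about $1/\text{days}$ for white
  noise;
* **IV** (intradaily variability)
  $= N \sum_i (x_i - x_{i-1})^2 \big/ (N-1)\sum_i (x_i - \bar x)^2$,
  about 2 for white noise, 4 in the perfectly alternating limit, small
  for smooth rhythms;
* **L5 / M10**: means of the least-active 5-h and most-active 10-h
  windows of the across-day average 24-h profile, slid circularly in
  1-bin steps (the across-day profile, not per-day windows, matching
  the common package default; midpoints are the circular window
  centres);
* **RA** (relative amplitude) $= (M10 - L5)/(M10 + L5)$.

Ties in the window search are broken deterministically: the earliest
starting window at or after 12:00 for L5 (night-anchored) and at or
after 00:00 for M10. Constant signals flag IS/IV/RA as undefined (`NA`)
instead of returning an arbitrary ratio, and IS is never clipped post
hoc.

# Speech features

A frame is silent when unvoiced *and* more than 25 dB below the
segment's maximum intensity; a pause is an internal silent run of at
least 0.3 s after trimming leading/trailing silence. These two
thresholds are common prosody practice (the source pipelines rarely
report theirs) and are arguments of `detect_pauses()`. From each quiet
segment with at least one pause — segments without pause are excluded
because pause behaviour is itself an outcome — six features are
computed: articulation rate (transcript syllables per second of
phonation time), pause duration mean and SD, pause rate (pauses per
second of total segment duration; the denominator is stated because
conventions differ), and F0 mean and SD over voiced frames only. For
Chinese transcripts the character count serves as the syllable count
(one character, one syllable). Sample (not population) SDs are used
throughout. Subject profiles average features across valid segments
unweighted, and F0 is tagged with sex so group statistics can be
stratified.

# Facial, language and diary features

Per video, each AU's feature is the proportion of frames (face
confidence at least 0.75; masked videos excluded) on which the AU is
present; per subject, the unweighted mean over the week's valid videos.
Word-category features are the percentage of transcript tokens matching
a lexicon category (exact match after whitespace normalisation; a token
may belong to several categories). The bundled Chinese lexicon with
`self_reference` and `negative_emotion` categories is a deliberately
small stand-in that makes the pipeline runnable — real analyses should
supply a full psycholinguistic dictionary via `read_lexicon()`. Mood
diaries yield the mean 0–10 happiness rating over completed entries and
the completion rate out of the scheduled 28 (7 days × 4 slots).

# Group statistics

`compare_two_groups()` screens each group with Shapiro–Wilk at
$\alpha = 0.05$ and uses Welch's t-test when both pass, otherwise a
two-sided Mann–Whitney U (exact for tieless samples of up to 20 per
group, continuity-corrected normal approximation otherwise — exactness
at toy sizes makes small fixtures reproducible). Normality screening is
per group: one non-normal group routes the pair to the nonparametric
branch. Three-group comparisons choose ANOVA or Kruskal–Wallis the same
way, with pairwise post hoc tests Bonferroni-corrected (raw p × 3,
capped at 1). Categorical contrasts use Pearson's chi-square without
continuity correction, matching the classical hand formula. Where
groups are not demographically matched, `adjusted_group_effect()` runs
OLS of the feature on group indicators plus age and sex. The branching
procedure's empirical type-I error and the regression CI coverage are
checked by simulation in the test suite (2,000 and 400 replicates).

# Classification

Feature sets follow fixed modality schemas: happiness (1), actigraphy
(17), facial AUs (5), voice (4: articulation rate and the three pause
features; F0 is excluded as sex-confounded), word categories (2), and
optionally the HADS-D score — 29 columns fused, 30 with HADS-D. The
17-feature actigraphy subset drops L5, M10, their midpoints and RA from
the 22-measure battery as largely redundant with the cosinor
parameters; the schema lives in `modality_columns()` and is recorded in
outputs. Assembly keeps complete cases for the chosen set, so the
usable n shrinks as modalities are added.

Two prediction targets are supported: lifetime MDD (all patients
positive) and non-remission (patients with a 17-item Hamilton score
above 7; 7 or lower with a lifetime history defines remission).

One-dimensional markers are thresholded by exhaustive cutpoint search
over midpoints of adjacent sorted values and both directions,
maximising sensitivity + specificity (balanced) or sensitivity + PPV
(imbalanced; selected automatically when prevalence < 0.3), with ties
broken toward higher specificity and then the lower threshold so
results are deterministic.

Multivariate sets are evaluated by leave-one-out cross-validation over
seven standard learners (RF 500 trees, logistic regression, RBF SVM,
5-NN, CART, Gaussian naive Bayes, and a single-hidden-layer network
with 16 units, decay 0.01, 300 iterations — hyperparameters are fixed
documented defaults in `model_defaults()`, with no tuning).
Standardisation is refitted inside every training fold to avoid
leakage. Fold seeds derive from the master seed and the held-out
subject's identifier, and subjects are processed in sorted-id order, so
results are reproducible and invariant to row order. Confusion ratios
with zero denominators (e.g. NPV with no predicted negatives) are
reported as missing, never as 0.

# The synthetic cohort generator

## Activity counts

Counts follow a two-state process. Nightly rest windows have a mean
onset and duration per group, jittered night-to-night by configurable
SDs. Outside rest, an epoch is mobile with probability
`mobile_prob_active`; mobile epochs draw a zero-truncated normal
(SD 25 counts by default) and immobile epochs a small exponential
(mean 1.5) capped below the mobility threshold. The mobile mean is
adjusted so the *marginal* expectation stays exactly on the cosinor
curve — this mean-compensation is what makes cosinor and `%mobile`
recovery well defined simultaneously. During rest, arousal epochs
(probability `mobile_prob_rest`) draw threshold-exceeding exponential
counts. The zero-truncated normal/capped-exponential pair keeps counts
nonnegative with controllable variance; with the default noise the
truncation bias on the cosinor mean is a fraction of a count.

## App streams

One video, speech segment and transcript are generated per completed
diary entry (Bernoulli completion per entry, independent — within-
subject correlation of adherence is not modelled because no published
estimate exists). Diary slots are fixed at 08:00 + 4-h steps; the slot
anchor is immaterial to every downstream feature. AU frames are
independent Bernoulli draws at the group presence rates with high
face-confidence values and occasional mask-flagged videos. Speech
segments alternate phonation intervals with gamma-distributed pauses
(resampled above 0.35 s so generated pauses survive the 0.3-s detection
definition), rendered as 10-ms voicing/F0/intensity frame tracks;
transcript syllable counts are tied to the articulation-rate preset
times phonation time, so articulation-rate recovery is exact in
expectation. Tokens are multinomial draws over the self-reference,
negative-emotion and filler vocabularies.

## Presets and what they do and do not emulate

The three shipped `group_profile()` presets (control, remitted,
non-remitted) are seeded from published group means: activity rhythm
location and amplitude, rest timing and duration, mobility rates, AU
presence rates, articulation and pause parameters, word-category
probabilities, happiness, completion rates, and clinical scale
locations. They reproduce the *direction* of the published contrasts
(lower mobile time, delayed acrophase and sleep midpoint, longer rest,
more brow lowering, less lip-corner pulling, slower articulation, more
variable pauses, more self-reference and negative-emotion words, lower
happiness and adherence in patients) and, for most features, roughly
their printed size. They are simulation presets, not ground truth.

Known divergences from real data, which bound what green tests prove:
within-subject day-to-day structure is simpler than reality, so IS from
simulated weeks is far higher than the ~0.56 typical of patients' data;
night-to-night sleep-duration variability uses a realistic 30–60-min
SD rather than the much larger values implied by reading published
unitless IIV magnitudes at face value; arousals are epoch-independent
rather than clustered; no naps, daytime rest, off-wrist periods,
weekday/weekend structure, or missing actigraphy days are generated;
per-subject feature separations are cleaner than in humans, so
simulated classifiers saturate (LOOCV F1 near 1) at sample sizes where
clinical F1 was ~0.8 — the classification tests validate the harness
(fold hygiene, metric identities, determinism, chance-level behaviour
under permuted labels), not clinical attainability.

## Reproducibility

A cohort is a pure function of its `cohort_config()`: the master seed
drives one sub-seed per subject, so a subject's data do not depend on
how many subjects precede it, and identical configs produce
byte-identical cohorts. The pipeline manifest records the seed and a
canonical config hash; rerunning a config reproduces identical outputs.

# Problem sizes used in the test suite

Simulation-based checks run at sizes chosen to keep Monte-Carlo error
well inside the asserted tolerances: 50 simulated weeks for cosinor
recovery; 500 replicates for the white-noise IV expectation; 200
subjects × 7 nights for sleep-timing jitter recovery (the expected
sample-SD attenuation at 7 nights, $c_4(7) \approx 0.96$, is well
inside the ±0.1 h band); 200 random instances per brute-force oracle;
2,000 replicates for the type-I error of the branching test; 400 for
regression CI coverage; and a 100-per-arm cohort for effect-direction
checks.

# Limitations

The package analyses extracted streams only; AU detection, F0 tracking,
speech recognition and word segmentation are upstream concerns. The
rest-interval detector and sleep scorer are transparent published-rule
analogues of proprietary clinical software, not re-implementations of
it, and will not numerically match its output on shared data. The
bundled lexicon is a toy; category percentages from it are only
meaningful relative to a real dictionary's coverage. Only single-
component 24-h cosinor models are fitted — no multi-component or
free-period variants, and no detrending.
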