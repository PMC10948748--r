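# digimood

Multimodal digital phenotyping of depression from one week of passive
and active monitoring. `digimood` is aimed at researchers who collect
wrist actigraphy together with app-based measures (short video/audio
diary entries and mood ratings) in case-control studies of major
depressive disorder, and who need a transparent, fully tested pipeline
from raw extracted streams to group statistics and cross-validated
classification.

The package covers:

* **Actigraphy** (minute-epoch counts): mobility (`%mobile`, counts at
  or above 4/min), average cpm by scope, automatic nightly
  rest-interval detection, weighted-window sleep scoring
  (`D_i = 0.04c_{i-2} + 0.2c_{i-1} + c_i + 0.2c_{i+1} + 0.04c_{i+2}`,
  sleep if `D < 40`), sleep duration/efficiency/midpoint and their
  night-to-night intra-individual variability (circular midpoints).
* **Circadian rhythm**: single-component 24-h cosinor by OLS
  (`y = MESOR + A·cos(2π(t − φ)/24)`; MESOR, magnitude `A`, acrophase
  `φ`) and the nonparametric suite IS, IV, L5, M10 and
  `RA = (M10 − L5)/(M10 + L5)`.
* **Speech**: pause detection on voicing/intensity frame tracks and the
  six prosodic features (articulation rate, pause mean/SD/rate, F0
  mean/SD over voiced frames).
* **Facial expression**: per-video action-unit presence proportions
  (AU1, AU4, AU6, AU12, AU15) with confidence and mask filters, averaged
  over the week.
* **Language and mood**: lexicon word-category percentages
  (self-reference, negative emotion) and diary happiness/completion
  summaries.
* **Statistics**: Shapiro–Wilk-driven two- and three-group tests
  (t / Mann–Whitney, ANOVA / Kruskal–Wallis) with Bonferroni post hoc
  correction, chi-square for categorical contrasts, and age/sex-adjusted
  regression.
* **Classification**: optimal cutpoints for one-dimensional markers and
  leave-one-out cross-validation of seven standard learners (RF, LR,
  SVM, KNN, DT, NB, ANN) over modality feature sets (29 fused digital
  features, 30 with HADS-D), reporting F1, sensitivity, specificity,
  PPV and NPV.
* **Synthetic cohorts**: a generator with per-group effect profiles
  (activity rhythm, rest timing and jitter, AU rates, prosody, word
  categories, mood, adherence, clinical scales) so the whole pipeline is
  testable without human data.

## Worked example

Simulate a 20-per-arm cohort with the shipped group presets, extract
features, compare groups, and run a fused-modality classifier:

```r
library(digimood)

cfg    <- cohort_config(n_control = 20, n_mdd = 20, seed = 42)
cohort <- generate_cohort(cfg)
cohort
#> <cohort> 40 subjects (control=20, mdd=20)

feats <- extract_features(cohort)
compare_feature_table(
  feats$app[c("happiness", "AU4", "AU12", "artic_rate", "pause_sd",
              "negemo_pct")],
  feats$subjects$group)
#>      feature mean_control sd_control n_control mean_mdd sd_mdd n_mdd test        p
#> 1  happiness        6.598     0.2516        20    5.052 0.3844    20    t 2.88e-16
#> 2        AU4       21.545     0.4626        20   29.866 0.6312    20    t 2.79e-33
#> 3       AU12       18.191     0.4908        20   10.390 0.4490    20    t 7.57e-37
#> 4 artic_rate        4.375     0.0129        20    3.972 0.0146    20    t 8.22e-46
#> 5   pause_sd        0.267     0.0377        20    0.333 0.0590    20    t 1.96e-04
#> 6 negemo_pct        0.308     0.1366        20    0.867 0.3471    20    t 5.32e-07
```

Patients show more brow lowering (AU4), less lip-corner pulling (AU12),
slower articulation, more variable pauses, more negative-emotion words
and lower happiness — the direction structure the presets encode. The
p-values are far smaller than in human data because simulated subjects
are cleaner than real ones; see the methods vignette for what the
generator does and does not emulate.

```r
fm <- assemble_features(feats)          # fused digital set, 29 features
ev <- loocv_evaluate(fm, model = "ann", seed = 42)
ev
#> <eval> ann n=40 (pos 20): F1 1.000 sens 1.000 spec 1.000 ppv 1.000 npv 1.000

fit_cosinor(cohort[["S001"]]$epochs)
#> <cosinor_fit> MESOR 154.36, magnitude 149.93, acrophase 15.15 h (n = 10080)
```

The whole-week cosinor on rest-gated data is biased relative to the
generating rhythm (MESOR 170, magnitude 129 for this arm) — an expected
property of fitting a pure cosine to a gated process, discussed in the
vignette.

A thin command-line front end over the same functions ships in
`inst/cli/digimood.R`:

```sh
Rscript inst/cli/digimood.R simulate --n-control 20 --n-mdd 20 --seed 42 --out cohort/
Rscript inst/cli/digimood.R features --in cohort/ --out feats/
Rscript inst/cli/digimood.R classify --features feats/ --task lifetime_mdd --seed 42 --out cls/
```

or drive everything from one YAML config with `run_pipeline()`.

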