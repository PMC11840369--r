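# cipnsense

Detecting chemotherapy-induced peripheral neuropathy (CIPN) from
smartphone sensor assessments.

CIPN — numbness, tingling and weakness in the feet (CIPN-f) and hands
(CIPN-h) — is a common, potentially irreversible toxicity of taxane and
platinum chemotherapy. Its objective signatures (increased postural sway,
gait instability, degraded tapping rhythm and dexterity) are measurable
with the inertial sensors and touchscreen of an ordinary phone.
`cipnsense` is an R package for building and stress-testing classifiers
that detect end-of-treatment CIPN from six remote functional assessments
(natural walk, tandem walk, tandem stance, Romberg stance, finger
tapping, hole-peg) alongside the CIPN20 patient-reported questionnaire,
and for asking *when* during treatment detection first becomes possible.

Because raw patient sensor data of this kind is not publicly deposited,
the package ships a first-class longitudinal cohort simulator that
emulates the study design (45 patients, baseline + per-cycle assessments
over ~12 weeks, CIPN-f/CIPN-h prevalences 24/45 and 29/45, foot
neuropathy expressed as amplified eyes-closed roll sway, hand neuropathy
as shifted tapping-interval dynamics), with tunable effect sizes
including exact nulls. Every statistical property the pipeline claims is
demonstrated against this generator.

## What the pipeline does

1. **Preprocessing** — walks are trimmed to the active phase (moving-RMS
   activity), split at the 180° turnaround (yaw-rate integration), and
   duration-filtered (< 7.5 s natural / < 10.5 s tandem legs discarded,
   strict comparison); all streams are rotated to a gravity-aligned,
   heading-aligned global frame via the device attitude quaternion.
2. **Features** — two-mode empirical mode decomposition per walk axis and
   a 4-band empirical wavelet transform per stance axis, each component
   summarized by 16 time/frequency statistics; tapping interval/drift
   features per hand (lag-k autocorrelation as the Pearson correlation of
   successive intervals); peg place/remove duration statistics. The
   registry holds 1564 provenance-tagged features.
3. **Selection** — ensemble minimum-redundancy-maximum-relevance (mutual
   information on quartile-discretized values, greedy chains stopped at
   non-positive score, chains seeded with the top-k relevant features)
   with three majority-voting steps: baseline per assessment (5 sets),
   end-of-treatment vs baseline per assessment (5 sets), cross-assessment
   pooling (15 sets). Selection sees training patients only.
4. **Models** — binomial elastic nets (glmnet) with infinite values
   imputed at 1.5× the finite training maximum, centring/scaling learned
   on training rows, a stratified patient-level 70/30 split, repeated CV
   with folds = repeats = round(√n), and a two-stage mixing/penalty grid.
   Three families per outcome: sensor-only, CIPN20-only, combined.
5. **Evaluation & comparison** — per-patient averaged probabilities,
   rank-statistic AUC, accuracy vs the no-information rate (one-sided
   exact binomial test), paired patient-level bootstrap AUC tests
   (400 resamples), monthly-window (M0–M3) AUC trajectories.
6. **Detection timeline** — daily 2×2 tables of carried-forward
   classification vs end-of-treatment diagnosis, two-sided Fisher exact
   tests, Benjamini–Hochberg correction, and the earliest day with
   sustained significance.

## A worked example

```r
library(cipnsense)

cfg <- pipeline_config(
  simulation = list(n_patients = 30, n_cycles = 3, sampling_rate = 50),
  comparison = list(n_boot = 200),
  seed = 42)
report <- run_pipeline(cfg)

f <- report$cipn_f
sprintf("sensor model: held-out AUC %.2f, accuracy %.2f vs NIR %.2f",
        f$models$sensor$auc, f$models$sensor$accuracy,
        f$models$sensor$nir)
f$models$sensor$importance_by_assessment[1]
f$earliest_day$sensor
f$windows[f$windows$model == "sensor", c("window", "n_patients", "auc")]
```

On this 30-patient cohort (about 2.5 minutes on one core) the run prints:

```
CIPN-f sensor model: held-out AUC 1.00, accuracy 0.78 vs NIR 0.67 (p = 0.38)
top assessment share: romberg_stance.eyes_closed (69.9%)
earliest sustained detection day: 63
 window n_patients       auc
     M0         30 0.5454545
     M1         30 0.8181818
     M2         30 0.8516746
     M3         30 1.0000000
```

Reading it: the foot-neuropathy sensor model separates the held-out
patients perfectly by rank (AUC 1.00 on a 9-patient test set — small-n
accuracy is far less impressive, and not significantly above the 0.67
majority-class rate). The eyes-closed Romberg phase carries ~70% of the
model's coefficient weight, the signature the simulator plants. Applied
longitudinally, the model is at chance before treatment (M0 AUC 0.55),
climbs monotonically as latent severity grows, and first achieves
sustained Fisher/BH significance on day 63 of treatment. The hand model
on the same run reaches AUC 1.00 with finger tapping carrying 66% of the
importance but never reaches a sustained detection day at this cohort
size.

The same machinery is exposed piecewise: `simulate_cohort()`,
`preprocess_session()`, `extract_all()`, `select_three_step()`,
`train_cipn_model()`, `evaluate_cipn_model()`, `bootstrap_auc_compare()`,
`windowed_auc()`, `detection_timeline()`. A minimal CLI wrapper lives at
`inst/cli/cipnsense.R` (`simulate`, `run-all`). The methods vignette
(`vignettes/cipn-detection-methods.Rmd`) documents the generator, every
tunable constant, and the design decisions.

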