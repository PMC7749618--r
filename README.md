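# alphassa

Adaptive singular-spectrum-analysis (SSA) extraction and classification of
resting-state EEG alpha rhythms.

## The problem

In 3–5-year-old children the posterior alpha rhythm often peaks below the
conventional adult 8–12 Hz band, so fixed-band power both underestimates
the oscillation and blurs group differences. `alphassa` is aimed at
researchers comparing two groups of subjects (e.g. autistic vs. typically
developing children) on occipital (O1/O2) resting EEG. It measures, per
subject:

- **iAPF** — the individual alpha peak frequency, the center of gravity of
  the power spectrum over 7–14 Hz:
  `CoG = Σ P(f)·f / Σ P(f)`;
- **iABP** — the absolute power `10·Σ xᵢ²` of the SSA-extracted alpha
  rhythm inside the subject's individualized band `0.8·CoG – 1.2·CoG`;
- fixed-band references **ABP#1** (`10·Σ P(f)` over 8–12 Hz) and **ABP#2**
  (time-domain energy of the SSA rhythm in 8–12 Hz),

and classifies the groups with a stratified 10-fold cross-validated linear
SVM, reporting fold accuracies and pooled-score ROC/AUC.

The core machinery is SSA: each 4-s epoch is embedded into an `L × K`
Hankel trajectory matrix (`L = 60`, `K = N − L + 1`), eigen-decomposed
through `X·Xᵀ`, and reconstructed into additive components by anti-diagonal
averaging. Ocular artifacts are removed adaptively (two leading components
when the epoch amplitude is high, otherwise one); the alpha rhythm is the
sum of component groups — linked by eigenvalue similarity
(`1 − λⱼ/λᵢ < 0.05`) and by matching FFT peak frequency — whose peak falls
in the target band.

Because comparable pediatric recordings are not publicly available, the
package ships a synthetic cohort generator with known ground truth
(subject-level peak frequency and amplitude, 1/f background, EOG bumps,
EMG bursts) that is used by the whole validation suite.

## Worked example

```r
library(alphassa)

cfg <- pipeline_config(
  cohort = cohort_spec(n_per_group = 10, duration = 120, seed = 5),
  seed = 5)
report <- run_pipeline(cfg)
print(report)
```

```
Alpha-rhythm pipeline report
  subjects analyzed: 20 (0 excluded)
  ASD: n = 10, iAPF 7.675 +/- 0.209 Hz
  TD: n = 10, iAPF 7.937 +/- 0.219 Hz
  group iAPF t = -2.737 (df 18.0, p = 0.014)
  feature set        accuracy    AUC
  ABP#1               85.00%     0.8800
  ABP#2               80.00%     0.9300
  iABP                75.00%     0.8800
  iAPF                70.00%     0.8000
  iABP+iAPF           85.00%     0.8600
```

Reading this: ten simulated subjects per group were preprocessed
(anti-aliased resampling to 200 Hz, 4-s epochs, 200-µV rejection), each
epoch was SSA-cleaned, and per-subject features were averaged over epochs
and the two occipital channels. The ASD group's measured peak frequency is
lower (7.68 vs 7.94 Hz; pooled t = −2.74) and each row shows one feature
set's 10-fold SVM accuracy and pooled-score AUC. At this small n the
fold-level accuracies are coarse (steps of 1/2 subjects per fold); the
validation suite runs 50 per group.

Lower-level functions are exported individually (`ssa_decompose`,
`clean_epoch`, `extract_rhythm`, `cog_frequency`, `crossval_linear_svm`,
...) — see the vignette `vignettes/adaptive-ssa-alpha.Rmd` for the model,
parameter meanings and design decisions. A thin command-line driver with
`simulate` / `features` / `classify` / `run` / `report` subcommands is
installed at `inst/cli/alphassa`.

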