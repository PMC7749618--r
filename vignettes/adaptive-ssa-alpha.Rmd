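---
title: "Adaptive SSA extraction of EEG alpha rhythms: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adaptive SSA extraction of EEG alpha rhythms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

In young children the posterior-dominant alpha rhythm often peaks *below*
the conventional 8–12 Hz adult band, so fixed-band power estimates can miss
most of the oscillation. `alphassa` implements an analysis built around two
subject-level features measured at the occipital electrodes O1/O2 of
resting-state EEG:

* **iAPF** — the individual alpha peak frequency, estimated as the
  center-of-gravity (CoG) frequency
  $\mathrm{CoG} = \sum_{f=n}^{m} P(f)\,f \;/\; \sum_{f=n}^{m} P(f)$
  over a wide search window $n=7$ to $m=14$ Hz. The CoG uses the whole
  shape of the alpha bump, which is more stable than the tallest-bin
  estimate when the peak is broad or split.
* **iABP** — the absolute power of the alpha rhythm extracted by singular
  spectrum analysis (SSA) inside the subject's *individualized* band
  $[0.8\,\mathrm{CoG},\ 1.2\,\mathrm{CoG}]$, measured in the time domain as
  $10\sum_i x_i^2$.

Two conventional-band references are carried along: ABP#1, ten times the
summed periodogram power over the fixed 8–12 Hz band, and ABP#2, the
time-domain energy of the SSA-extracted rhythm in that same fixed band.
A stratified 10-fold linear SVM then classifies two groups of subjects
from each feature set (and from iABP + iAPF jointly), with pooled
decision-score ROC/AUC as the headline evaluation.

# The SSA model

Each 4-s single-channel epoch $S = (S_1,\dots,S_N)$ is embedded into the
$L \times K$ Hankel trajectory matrix ($K = N-L+1$) whose columns are
lagged windows. Eigen-decomposition of $XX^\top$ gives eigenvalues
$\lambda_1 \ge \dots \ge \lambda_L \ge 0$ (squared singular values of $X$)
and left singular vectors $u_i$; each rank-1 term
$u_i u_i^\top X$ is mapped back to a series — the *reconstruction
component* (RC) — by anti-diagonal averaging. The RCs sum exactly to the
input, and $\sum_i \lambda_i$ equals the squared Frobenius norm of $X$;
both identities are enforced by tests at $10^{-8}$ relative tolerance.
Implementation note: the anti-diagonal average of a rank-1 outer product is
a normalized linear convolution of its two factors, so RCs are computed
with one batched FFT instead of materializing each $L \times K$ term.

**Adaptive ocular-artifact removal.** Blinks and eye movements (EOG)
produce large, slow deflections whose energy dominates the leading SSA
subspace. Per epoch: if the peak absolute amplitude exceeds
`eog_amp_threshold` (default 100 µV, a typical blink amplitude floor) the
two largest-eigenvalue components are removed, otherwise only the largest.
The price of this simple rule is that in clean epochs the largest component
is usually one member of the alpha pair itself; the remaining member keeps
the peak frequency intact, and since the same rule is applied to every
subject the energy scaling cancels in standardized classification.

**Rhythm grouping.** A sinusoid occupies a *pair* of near-equal
eigenvalues. Components are first linked when adjacent sorted eigenvalues
satisfy $1 - \lambda_{i+1}/\lambda_i < K$ with $K = 0.05$ (applied to
adjacent pairs only and chained transitively; an all-pairs rule would
over-merge across the spectrum). Components are then merged by
single-linkage on their FFT peak frequencies with a tolerance of one FFT
bin (0.25 Hz at 4 s / 200 Hz) — "the same peak frequency" is only
meaningful at bin resolution. Groups whose eigenvalue-weighted mean peak
falls inside the target band are summed to give the extracted rhythm; if
no group qualifies the result is an all-zero series flagged
`empty_band`.

# Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `fs_target` | 200 | Hz | analysis rate; alpha band sits far below Nyquist |
| `epoch_seconds` | 4 | s | 0.25-Hz spectral resolution; standard artifact unit |
| `amp_threshold` | 200 | µV | gross-artifact epoch rejection (pediatric practice) |
| `eog_amp_threshold` | 100 | µV | switches 1- vs 2-component EOG removal |
| `L` | 60 | samples | SSA window (0.3 s at 200 Hz) |
| `C` | 12 | — | leading RCs considered for rhythm grouping |
| `k_sim` | 0.05 | — | eigenvalue-similarity threshold for periodic pairs |
| `cog_n`, `cog_m` | 7, 14 | Hz | CoG search window (child alpha sits low) |
| `fixed_band` | 8–12 | Hz | conventional reference band for ABP#1/#2 |
| `cv_folds` | 10 | — | stratified CV folds |
| `svm_cost` | 1 | — | linear-SVM regularization |

Feature aggregation: features are computed per epoch and channel, averaged
over epochs, then over O1/O2 (so iABP + iAPF is a 2-dimensional feature
vector); `keep_channels = TRUE` keeps per-channel columns for sensitivity
analyses. The individualized band is fixed from the channel's epoch-mean
CoG and then held while re-extracting the rhythm for iABP (a two-pass
design: the band is determined *by* the iAPF, then applied). The spectrum
estimator is the epoch-mean rectangular-window periodogram — the simplest
estimator consistent with the 4-s epoch unit; Welch-style tapering would
trade bias for variance without changing any downstream contract.
Epoch rejection is applied jointly across channels (an artifact anywhere
discards the epoch) and after resampling; the order is configurable in
principle but resampling first keeps the threshold meaningful at one rate.

# The synthetic cohort generator

Real pediatric recordings cannot be redistributed, so validation runs on
synthetic cohorts whose *statistical structure* matches what the pipeline
assumes. Per subject, each channel is the sum of:

* a narrowband alpha process: an amplitude-modulated sinusoid at the
  subject's peak frequency $f_0$ (drawn once per subject, shared across
  channels), modulation depth 0.3 with envelope bandwidth
  `alpha_bw`/2 — chosen over filtered noise so the ground-truth peak
  frequency is *exact*, which makes recovery tests sharp;
* $1/f$ background noise (spectral shaping of white noise, default
  exponent 1, RMS `bg_scale`);
* Poisson-timed raised-cosine EOG bumps (smooth, band-limited,
  endpoint-zero), shared across channels;
* Poisson-timed 0.2-s EMG bursts of 50–90 Hz band-passed noise (only
  relevant before resampling).

Group defaults: TD iAPF 7.92 ± 0.21 Hz, ASD 7.54 ± 0.23 Hz — the reported
occipital group statistics for 3–5-year-old cohorts; alpha amplitude TD
20 ± 3.5 µV vs ASD 14 ± 3.0 µV (ASD 30% lower), chosen once so the latent
amplitude effect size ($d \approx 1.8$, AUC ≈ 0.9) matches the published
single-feature classification performance this analysis emulates.
Remaining values are realistic resting-EEG choices fixed a priori:
`alpha_bw` 1 Hz, `bg_scale` 3 µV, EOG 6/min at 150 µV for 0.5 s, EMG 3/min
at 30 µV. Recordings default to 5 min at 1,000 Hz; the montage helper
lists F3, F4, Tp7, Tp8, P3, P4, O1, O2, but only the analysis channels are
synthesized by default to keep cohorts light. Subject draws come from
deterministic child seeds, `(48271 * cohort_seed + 10007 * index) mod
(2^31 - 1)`, so cohorts are bit-reproducible from their spec.

What the generator does *not* model: per-channel iAPF offsets (no
within-subject cross-channel statistics are available to calibrate them),
volume conduction or any forward head model, non-stationary state changes,
or realistic EOG topography (bumps hit all channels equally so that the
occipital cleaning stage is actually exercised). Passing tests therefore
demonstrate correctness of the *pipeline* under the assumed signal
structure, not clinical performance on real EEG.

# Numerical choices and degenerate inputs

* Indexing is 1-based throughout (R convention); epochs are half-open
  sample blocks of exactly `round(fs * epoch_seconds)` samples, trailing
  partial epochs discarded.
* Resampling is a zero-phase FFT low-pass — flat to `0.4 * fs_target`,
  raised-cosine roll-off reaching zero at `0.45 * fs_target` — followed by
  decimation (integer ratios) or polyphase resampling (other rational
  ratios). Zero phase means no group-delay bookkeeping at the band of
  interest; a 95-Hz tone survives a 1,000→200 Hz conversion at below
  $10^{-12}$ of its input RMS.
* FFT peak picking excludes the DC bin and breaks ties toward the lower
  frequency (determinism; DC is trend, not rhythm).
* Numerically-zero components (eigenvalue below $10^{-9} \lambda_1$) are
  excluded from rhythm grouping — their FFT argmax is noise.
* All-zero epochs decompose to all-zero RCs without error; an all-zero
  extracted rhythm is flagged rather than fatal; subjects whose epochs are
  all rejected, or whose spectra carry no power in the CoG window (e.g.
  constant channels), are excluded with a recorded reason and the run
  continues; a run aborts only when fewer than two subjects per group
  remain.
* The pooled two-sample t is the default group test (a Welch variant is
  available via `var_equal = FALSE`); reported p-values are raw,
  uncorrected — exactly two electrode-level tests are ever reported.
  Decision-score ties contribute one half to the AUC (Mann–Whitney
  convention), and the ROC threshold sweep moves tied scores as one block
  so its trapezoid area equals the rank statistic identically.

# Design choices that were genuinely open

* **Eigenvector convention.** The $u_i$ are taken as eigenvectors of
  $XX^\top$ and $v_i$ of $X^\top X$ (the standard SVD pairing), which is
  the only dimensionally consistent reading of the decomposition.
* **AUC pooling.** The single AUC per feature set is computed on decision
  scores pooled across the ten held-out folds; per-fold AUCs at ~11
  subjects per fold would be too unstable to summarize.
* **Stratified folds with within-fold z-scoring.** Plain random folds can
  produce one-class test folds under a 46/63-style imbalance; linear SVMs
  are scale-sensitive and iABP (energy) and iAPF (Hz) are incommensurate,
  so standardization uses training-fold statistics only.
* **Energy units.** The $\times 10$ factor in both energy definitions is
  reproduced literally (not reinterpreted as dB); the time-domain energy
  is treated as absolute energy, which is how it is used even where prose
  calls it "relative". Frequency-domain band sums run over all
  full-resolution bins inside the closed band interval.
* **Test problem sizes.** The end-to-end recovery test uses 50 subjects
  per group at 5-min recordings, the null (identical-group) test 50 per
  group at 1-min recordings — the null property concerns labels, not
  spectral resolution, so shorter recordings suffice.

# Known limitations

* The CoG estimator is mildly biased toward the center of the 7–14 Hz
  window when background power is non-negligible; with default settings
  this compresses a 0.38-Hz group difference by roughly 0.05 Hz. This is a
  property of the estimator (and of any windowed CoG), not of the
  generator.
* Removing the largest component from clean epochs discards about half of
  the alpha pair's energy; absolute energies are therefore comparable
  *within* an analysis but not with fixed-band power from other toolchains.
* EDF input/output is not provided; cohorts travel as per-subject CSV with
  YAML sidecars and a manifest.
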