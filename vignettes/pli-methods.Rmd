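---
title: "Phase lag index connectivity for two-group resting EEG: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phase lag index connectivity for two-group resting EEG: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(eegpli)
```

## The measure

The phase lag index (PLI) between two signals is

$$\mathrm{PLI} = \left| \left\langle \operatorname{sign}\,\Delta\phi(t_k) \right\rangle \right|,$$

the absolute time-average of the sign of their instantaneous phase
difference, with $\Delta\phi$ wrapped to $(-\pi, \pi]$ and
$\operatorname{sign}(0) = 0$. It is 0 when phase differences are symmetric
around zero and 1 when one signal consistently leads or lags the other. The
point of the sign is volume conduction: a single cortical source seen by two
scalp electrodes produces *zero-lag* correlation, whose phase-difference
distribution is symmetric around zero and therefore contributes nothing to
PLI, whereas genuine delayed interaction produces a consistent non-zero lag
and drives PLI toward 1.

A historical note on conventions: some descriptions label PLI "0 for
complete synchronization"; we implement the standard estimator, in which 0
means *no consistent non-zero lag* — which includes perfect zero-lag
synchronization — and 1 means perfect non-zero-lag locking.

Because the estimator is the absolute value of a mean of $\pm 1$ signs, it
has a positive finite-sample floor under independence:
$E[\mathrm{PLI}] \approx \sqrt{2 / (\pi N)}$ for $N$ independent phase
samples. Band-filtered EEG phases are autocorrelated over roughly the
inverse bandwidth, so the *effective* $N$ inside a 3-s epoch is far smaller
than the sample count, and observed floors (about 0.2 per epoch for the
alpha band) are correspondingly higher. Tests against the analytic floor are
therefore run on independently drawn phases, while generator-level tests
compare against an empirical floor computed under the same autocorrelation.

## Phase extraction

Each epoch and channel is band-filtered with a zero-phase fourth-order
Butterworth band-pass, the analytic signal is computed in the frequency
domain, and its angle gives the instantaneous phase. Ten percent of samples
at each epoch end are discarded (`edge_trim = 0.1`, configurable) to
suppress filter and analytic-signal edge effects. PLI is computed within
each 3-s epoch and averaged across epochs; pooling all samples into one
estimate is available via `aggregate = "pooled"`.

Band definitions: delta 1–4 Hz, theta 4–8 Hz, alpha 8–13 Hz, beta 13–30 Hz.

## Filtering

All filters are Butterworth designs applied forward–backward (zero phase),
so phase estimates downstream are not biased by filter delay. Two numerical
choices deserve a note:

* **Second-order sections.** A 0.1 Hz high-pass at 1000 Hz has poles so
  close to the unit circle that a single transfer-function realisation is
  numerically fragile. Filters are therefore designed directly as biquad
  cascades and each biquad is run forward–backward in compiled code with
  short odd-reflection padding and steady-state initial conditions. The
  test suite cross-checks the cascade against an independent zero-phase
  filtering implementation on well-conditioned designs and asserts the
  passband/stopband contracts directly.
* **High-pass + low-pass cascade.** The 0.1–30 Hz band-pass is realised as
  a high-pass followed by a low-pass. The passband contract is asserted in
  tests: a 10 Hz tone passes within 5%, an 80 Hz tone is attenuated by more
  than 40 dB, a 50 Hz tone by more than 30 dB through the 48–52 Hz notch.
  One practical caveat the tests also encode: the 0.1 Hz stage has a
  roughly 10-s impulse response, so any measurement of its behaviour must
  use windows long enough that boundary effects cannot reach the evaluated
  region.

The preprocessing chain runs in a fixed, logged order: drop EOG channels
(HEO/VEO), re-reference to linked mastoids (average of M1/M2, synonyms
A1/A2; the stage is skipped with a log note when no mastoid channels exist),
band-pass 0.1–30 Hz, notch 48–52 Hz, downsample to 500 Hz (plain
decimation — the 30 Hz low-pass has already removed everything near the new
Nyquist), segmentation into non-overlapping 3-s epochs, and peak-amplitude
epoch rejection. The rejection rule (default threshold 100 amplitude units)
is a deterministic stand-in for the manual/ICA artifact screening used on
real recordings; it preserves the stage contract (epochs in, fewer epochs
out, surviving indices recorded) without attempting to model biological
artifacts.

## The synthetic cohort generator

No patient recordings are distributable, so the package ships a generator
whose ground truth is known. Each channel is

$$x_c(t) = s \sum_b \kappa_b\, m_c\, \mathrm{Re}\!\left[a_b(t)\, e^{-i\phi_c}\right] + \sigma\, \varepsilon_c(t),$$

where $a_b$ is the unit-variance analytic signal of band-limited Gaussian
noise (one shared oscillator per classical band), $\phi_c$ a per-channel
phase lag (default evenly spaced over $[0, 0.8\pi]$), $m_c$ a regional gain
(default 1.3 on central/parietal/parieto-occipital channels, emulating the
posterior concentration of resting alpha coupling), $\varepsilon_c$
independent pink noise (resting EEG is 1/f-like; white noise is available
for unit tests), and $s = \sigma = 10$ amplitude units by default so
$\kappa_b$ reads as a source-to-noise amplitude ratio.

The per-channel lag is implemented as a constant rotation of the source's
analytic signal rather than a time shift. The rotation gives an exactly
constant instantaneous phase offset at every frequency in the band — the
noiseless PLI between channels with different lags is exactly 1, which makes
the generator's ground truth analytic — and costs one complex multiplication
per channel. A time shift would make the offset frequency-dependent across
the band and require two FFTs per channel for the same effect.

Default oscillator strengths are $\kappa =$ 0.6 (delta), 0.6 (theta),
1.0 (alpha), 0.4 (beta): eyes-closed resting EEG is alpha-dominated. A small
flag adds mastoid/EOG channels and high-amplitude spikes so the full
preprocessing chain (re-referencing, rejection) can be exercised end to end.

### Cohort structure and calibration

A cohort draws per-subject alpha coupling
$\kappa_i = \kappa_\alpha \cdot g \cdot e^{\eta_i}$, with
$\eta_i \sim N(0, 0.15^2)$ and $g$ = `group_effect` in the patient (MCI)
group, 1 in controls. The 15% between-subject jitter is what makes global
alpha PLI a subject-level variable rather than a constant.

The MoCA cognitive score is linear in the *latent* coupling:
$\mathrm{MoCA}_i = \alpha_g + \beta_g \kappa_i + e_i$. The measured global
alpha PLI has no closed form under additive noise, so the generator stores
the latent coupling as its ground truth (`true_alpha_coupling`) and the
implied coupling–MoCA Pearson correlation is known exactly:
$r = \beta_g\,\mathrm{sd}(\kappa) / \sqrt{\beta_g^2 \mathrm{var}(\kappa) + \mathrm{sd}(e)^2}$.
Defaults plant a moderate correlation (~0.48) in the patient group and a
weak one (~0.27) in controls, with group MoCA means/SDs near 22.1 ± 2.2 and
28.1 ± 1.4; clinical covariates (age, education, sex, diabetes duration)
are drawn from matched-group distributions. Because the measured PLI is a
noisy monotone transform of $\kappa_i$, the correlation observed between
measured PLI and MoCA is attenuated relative to the latent value — the
pipeline-level check asserts a positive, significant patient-group
correlation rather than the latent closed form.

`group_effect` has no counterpart value in the literature (only the
significance of the group difference is reported), so it was calibrated
once, before the acceptance suite was frozen, against the detection-power
property at the reduced study conditions (30 + 30 subjects, 8 channels at
128 Hz, 60 three-second epochs); the default is 0.8, and the acceptance
suite verifies detection power of at least 90% there, with type-I error
near the nominal 5% when the effect is switched off. All recovery
simulations in the tests and the acceptance script run at those reduced
conditions; the full study conditions (62 channels, 1000 Hz, 300 s) remain
the generator defaults.

Reproducibility uses one master seed: covariates and couplings come from the
master stream, and each subject's recording seed is drawn from it once, so
subjects are independent and any subject can be regenerated in isolation.

## Group statistics

Continuous clinical covariates are compared with the pooled-variance
Student t (computable directly from printed mean ± SD summaries, which is
how the published table is checked), sex with the Pearson chi-square on the
2×2 table *without* continuity correction — the uncorrected statistic is
what reproduces the published 0.601 — and PLI variables with the Wilcoxon
rank-sum test (tie-corrected normal approximation with continuity
correction; the exact distribution is used automatically for n ≤ 10 without
ties, which is also how the enumeration oracle test is possible). The
normality gate is Shapiro–Wilk at α = 0.05. Per-pair comparisons report raw
p-values by default — 1891 simultaneous tests at 62 channels — with an
optional Benjamini–Hochberg column; the default mirrors the analysis being
reproduced, the option is the principled alternative.

Two cells of the published cohort table are knowingly *not* reproducible
from the printed rounded summaries: recomputing from the printed age and
MoCA mean ± SD gives −0.509 and −12.42 against printed −0.515 and −11.350
(presumably computed on unrounded data). `validate_table1()` reports these
as informational rows; the gender, education and duration cells reproduce
exactly at three decimals.

## Classification

A ridge-stabilised logistic regression (IRLS with a $10^{-6}$ L2 penalty on
slopes; 1000× penalty fallback under separation) is evaluated by stratified
10-fold cross-validation with the patient group as the positive class.
Features are z-scored using training-fold statistics only. Accuracy,
sensitivity, specificity, precision and F1 come from the single confusion
matrix pooled over all held-out folds at a 0.5 threshold; AUC comes from the
pooled held-out probabilities via the rank (Mann–Whitney) formula with ties
counted ½. Pooling was chosen over fold-averaging because per-fold test sets
of six subjects make fold-wise AUCs ill-defined. The default feature set is
the global alpha PLI plus the eight named electrode pairs when the montage
contains them ("`global_pairs8`"); `global` and `all_pairs` modes cover the
other plausible readings of "alpha PLI measures".

The **empirical chance level** is the 95th percentile of the accuracy
distribution obtained by re-running the complete cross-validation under
uniformly random label permutations (5000 by default; reduced counts are
used in tests). Observed accuracy above this level corresponds to p < 0.05.
Two calibration facts are asserted in the acceptance suite: for balanced
n = 60 uninformative data the chance level lies strictly inside (50%, 75%)
— finite-sample inflation above 50% is expected and real — and under null
data the observed accuracy exceeds the chance level in about 5% of
replicates.

## Pipeline and problem sizes

`run_study()` chains synthesis (or ingestion of on-disk recordings),
preprocessing, connectivity, statistics and classification from one config,
writes each result as CSV/JSON plus a parameter-complete run log, and is
byte-reproducible under a fixed master seed. Per-subject connectivity can be
cached content-addressed (`cache = TRUE`) so reruns skip unchanged stages.
Figures (connectivity heatmap, ROC) are behind a flag so the pipeline is
testable headless.

The default `study_config()` is a reduced demonstration of the study design:
two groups of 30, five-minute recordings on a 16-channel montage at 500 Hz
(downsampled to 250 Hz), 500 label permutations. At this scale a full run
takes a few minutes on one CPU. Recovery simulations use the 8-channel,
128 Hz, 60-epoch configuration described above. These sizes are the
package's chosen defaults for demonstration and testing; the generator's
recording defaults match the full acquisition protocol (62 channels,
1000 Hz, 300 s) and the pipeline accepts them unchanged.

## What passing tests do and do not show

The generator emulates the *statistical skeleton* of a resting-state EEG
cohort study: band-limited shared oscillators with stable phase lags,
1/f background noise, a group difference confined to alpha coupling, a
cognition score tied to that coupling, and matched clinical covariates. It
does not emulate volume-conduction mixing matrices, non-stationary alpha
bursts, eye/muscle/cardiac artifacts (beyond optional test spikes),
electrode impedance drift, or any spatial correlation structure in the
noise. Passing the recovery tests therefore shows that the estimator and
pipeline do what they claim on data with known truth — not that identical
numbers would be obtained on clinical recordings. Conversely, the
published-table checks and the estimator oracles (sign-average definition,
AUC pair counting, rank-sum enumeration) are exact and carry over to any
data.

## Known limitations

* ICA-based artifact removal is not implemented; the amplitude rule is a
  stand-in with the same pipeline contract.
* No EDF reader: recordings enter either from the generator or from the
  plain-text matrix format (`write_recording()` / `read_recording()`).
* PLI is the only connectivity measure; weighted PLI, coherence and graph
  metrics are out of scope.
* The rank-sum normal approximation is used for all n > 10; at n = 30 per
  group the exact distribution is unnecessary and unavailable under ties.
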