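---
title: "Multiband spectral-entropy analysis of prefrontal fNIRS for motion-sickness classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multiband spectral-entropy analysis of prefrontal fNIRS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fnirsms)
```

## The problem and the signal model

Motion sickness during a car ride is accompanied by changes in prefrontal
hemodynamics. A continuous-wave fNIRS device measures, per optode channel,
the intensity of near-infrared light at two wavelengths (defaults 730 and
850 nm) after it traverses scalp, skull, and cortex. Over a session the
intensity fluctuates with the concentrations of oxy- and deoxyhemoglobin
(HbO, HbR), whose absorption spectra differ between the two wavelengths, so
that the two intensity series per channel determine both concentration
changes.

The analysis assumes the hemodynamic signal below 2 Hz is a superposition of
five oscillatory regimes — cardiac (0.6–2.0 Hz), respiratory (0.145–0.6),
myogenic (0.052–0.145), neurogenic (0.021–0.052), and endothelial metabolic
activity (0.0095–0.021 Hz) — and that the *spectral complexity* of these
bands, not their amplitude, carries the sickness information. Complexity is
quantified by the normalized power-spectral entropy of each band-limited
series, and a radial-basis-function SVM maps the five entropies to a binary
sickness label obtained from the subject's own 6-point rating (0–1 = well,
2–5 = sick).

## Pipeline stages and their parameters

### Trimming and filtering

The first `trim_initial_s` seconds (default 300 s) are discarded: the
subject sits still before the ride and those samples carry no labels. Each
intensity series is then mean-filtered and median-filtered with centered
windows (`mean_window`, `median_window`, default 5 samples = 0.5 s at
10 Hz). The windows are deliberately short: a 0.5 s window attenuates
sample-level noise and isolated outliers while leaving the cardiac band
(≤ 2 Hz) essentially untouched. The mean filter truncates its window at the
boundaries; the median filter pads by edge replication — both conventions
keep the output the same length as the input and are fixed so results are
bit-reproducible.

### Motion-artifact suppression

Probe movement produces spikes and transient baseline shifts that are far
larger than hemodynamics. The series is decomposed with a 5-level db5 DWT;
within each detail level the robust scale `1.4826 · MAD` estimates the
clean-coefficient spread, and coefficients beyond `mas_threshold_k` times
that scale (default k = 3) are clipped to the threshold (not zeroed —
clipping preserves the underlying signal's contribution at that
time-scale). On clean signals whose detail coefficients stay under the
threshold at every level the operation is an identity up to reconstruction
error, which the tests verify. The threshold rule is deterministic and has
no tuning beyond k; k = 3 corresponds to the usual 3-sigma convention for
Gaussian-like coefficient distributions.

Suppression is applied to the intensity series, before conversion, because
the artifact mechanism (optode displacement) is optical, not hemodynamic.

### Modified Beer–Lambert conversion

Per channel, optical-density changes are
`dA(lambda, t) = -ln(I(lambda, t) / I0(lambda))` with the baseline
`I0` defined as the mean intensity over the first 30 s after trimming — the
convention must be explicit because entropies of band series are invariant
to it (the DC offset lives in the DWT approximation, which the band
reconstructions exclude), but the concentration traces themselves are not.
The two-wavelength system
`dA(lambda) = sum_s eps(lambda, s) dC_s L DPF(lambda)` is solved exactly
(2×2) for (ΔHbO, ΔHbR). The shipped extinction coefficients
(0.390/1.102 and 1.058/0.691 cm⁻¹mM⁻¹ for HbO/HbR at 730/850 nm),
pathlength 3 cm, and DPF 6 are representative literature constants; any
published tabulation can be substituted through `extinction_matrix()`, and
only HbO is analyzed downstream (its signal-to-noise ratio is higher; ΔHbR
is computed and kept for completeness).

### Channel selection

Six prefrontal channels are redundant; PCA across channels of the
session's post-trim ΔHbO matrix finds the direction of maximum variance,
and the channel with the largest absolute PC1 loading is retained. Two
genuinely open choices are fixed here: (i) selection uses |PC1 loading|
alone by default (PC1 is the maximum-variance direction; a combined
PC1–PC2 norm rule is selectable via `channel_rule = "pc12_norm"`), and
(ii) PCA is fitted once per session rather than per epoch (the per-epoch
alternative is available via `channel_scope = "epoch"`), because a single
physical channel per subject keeps features comparable across that
subject's epochs. Eigenvector signs are fixed (largest-magnitude entry
positive) so results are deterministic; ties break to the lowest channel
index.

### Band decomposition

Epochs of 300 s at 10 Hz (3000 samples) are decomposed with a 9-level db5
DWT. Level-j details of a dyadic DWT occupy the ideal sub-band
`[fs/2^(j+1), fs/2^j]`; each analysis band is assigned the detail level
with the largest fraction of its *own* sub-band width inside the band,
requiring at least 50% containment, with ties resolved toward the finer
level. At 10 Hz this containment rule yields the mapping I:d3, II:d5,
III:d6, IV:d8, V:d9 and requires exactly 9 levels (8 leave band V
uncovered) — the rule generalizes the fixed printed mapping to other
sampling rates and band tables. The band edges and the dyadic sub-band
edges do not coincide exactly (band II is 0.145–0.6 Hz while d5 spans
0.156–0.3125 Hz); the mapping, not the nominal edges, defines the
computation, and since db5 has finite transition bands the tests assert
energy capture thresholds (≥ 60% for an in-band tone) rather than
brick-wall behavior.

Boundary handling defaults to symmetric extension (least edge distortion
on finite epochs); periodization is available and is the mode under which
the transform is exactly orthogonal, conserving energy to 1e-8 relative on
lengths divisible by 2^levels. Both modes reconstruct perfectly; the
filter bank was validated against an independent reference implementation
(frozen oracle vectors in the test suite).

### Spectral entropy

For a band series of length N, `S_x(k) = |X(k)|^2 / N` over the full
two-sided DFT (k = 0..N−1), so that `sum_k S_x(k) = sum_n x_n^2` holds
exactly (Parseval); `p_k = S_x(k)/sum S_x`; `F_SE = -sum p_k log2 p_k`
with `0 log 0 = 0`; `F_PSE = F_SE / log2 N`. The two-sided convention
matters: it fixes the normalizing constant `log2 N`, and with it the
attainable extremes — F_PSE = 1 iff the spectrum is uniform, 0 iff a
single bin carries all power. Entropy is computed on the reconstructed
full-length band series, not on the wavelet coefficients, and no
detrending or windowing is applied by default (a Hann window is available
but off, so the plain periodogram remains the reference definition). The
entropy is invariant to amplitude scaling, which is why the generator's
sickness effect must act on spectral shape.

### Classification

Ratings are binarized (0–1 vs 2–5). A 5-fold cross-validation shuffles
epochs with a seeded permutation into folds of near-equal size
(16/16/16/15/15 at n = 78); per fold, standardization statistics are
computed on the training portion only, an RBF-SVM (C = 1, gamma = scale
rule; both exposed, since the original hyperparameters are unknown and
should not be presented as fixed truths) is trained, and the held-out fold
predicted. Confusion counts are pooled over folds into one matrix for the
whole dataset; precision/recall/F1 accompany accuracy, with undefined
ratios reported as missing rather than zero. Plain shuffled folding is the
default (matching a pooled 78-epoch treatment); subject-stratified folding
is deliberately out of the default path but the feature table retains
`subject_id` so users can fold by subject themselves.

## The synthetic study generator

No public recordings of this protocol exist, so the generator emulates the
study design: 13 subjects, one 30-minute session each, a 5-minute
stationary pre-segment, ratings every 5 minutes → 78 labeled epochs at
10 Hz. Per epoch and channel, ΔHbO is a sum of five band components — a
sinusoid at the band's center frequency (1.1, 0.25, 0.09, 0.032, 0.014 Hz)
whose instantaneous frequency wanders as an AR(1)-smoothed deviation with
relative bandwidth `jitter_frac` (default 0.04) — plus 1/f background
noise. The sickness state widens the jitter bandwidth by
`1 + effect_size` (defaults 1.5, 1.0, 0.6, 0.35, 0.2 for bands I–V),
raising the band's spectral entropy; the effect is strongest in the
cardiac band and weakest in the endothelial band, so the per-band
entropy–label correlations have a built-in ordering the tests can check.
Amplitudes (0.4–1.0 µM, growing toward the slow bands) and noise level
(0.3 µM) follow the usual physiological picture in which slow vasomotor
oscillations dominate the cardiac pulsation; ΔHbR is an anticorrelated
copy (−0.3) with independent noise. Concentrations are forward-projected
to intensities through the same Beer–Lambert model the pipeline inverts
(round-trip exact to 1e-9 on noise-free input), one channel per subject
carries the band signal at 5× amplitude so channel selection has a ground
truth, and Poisson-placed artifacts (0.5/min, ±20% intensity; 1–3-sample
spikes and 2–10 s transient baseline shifts) contaminate the intensities.
Transient — rather than permanent — shifts are the modeled artifact class
because detail-level thresholding is a time-scale-limited operation: a
displacement that never settles back is indistinguishable from a true
baseline change at the scales the 5-level decomposition can see.

What the generator does *not* emulate: hemodynamic response functions,
vehicle dynamics, vestibular physiology, inter-subject variability in
effect direction, or any coupling between bands. Passing end-to-end tests
therefore demonstrates that the chain recovers the statistical structure
it assumes — spectral broadening expressed through band entropies — not
that real riders' sickness is classifiable at any particular accuracy.

## Numerical conventions and degenerate inputs

* Filters reject even windows; window 1 is the identity.
* All-zero epochs have an all-zero spectrum and raise an "undefined
  entropy" error rather than returning a value.
* Constant channel matrices (zero covariance) are a PCA error.
* Singular extinction matrices (proportional wavelength rows) are rejected
  at construction.
* The sampling rate must exceed twice the highest band edge (Nyquist
  guard): 10 Hz passes for a 2 Hz cardiac edge, 3 Hz errors.
* Every stochastic step (generation, artifact placement, fold shuffling)
  derives its stream from one integer seed; identical (inputs, config,
  seed) give byte-identical feature tables and reports.

## Problem sizes used in the tests

The test suite exercises the full default study (13 subjects, 78 epochs)
end-to-end across 10 seeds for the effect condition and 10 for the
zero-effect control, property checks on 100–1000 random sequences, and
100-replicate channel-recovery trials; single-epoch checks use 3000-sample
epochs throughout. These sizes are the package's chosen benchmark
conditions: large enough that chance-level behavior (≈ 0.5 accuracy at
n = 78) and strong-effect behavior (pooled accuracy well above 0.85)
separate cleanly, small enough to run routinely.

## Known limitations

* Only HbO-based features are implemented; ΔHbR is computed but unused
  downstream.
* The band/level assignment assumes dyadic sub-bands; strongly non-dyadic
  band tables can be uncoverable at any depth and will error rather than
  approximate.
* Wavelet MAS cannot remove artifacts slower than its deepest detail
  level; permanent baseline shifts survive by construction.
* The SVM hyperparameters are defaults, not tuned values; a grid search is
  intentionally not run by default.
* CSV is the only on-disk format; SNIRF/HDF5 import is out of scope here.
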