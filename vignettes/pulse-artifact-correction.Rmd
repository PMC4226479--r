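---
title: "Pulse-artifact correction for EEG recorded in the MR scanner: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Pulse-artifact correction: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

EEG acquired during simultaneous fMRI is contaminated by the
ballistocardiogram or pulse artifact (PA): every heartbeat moves the head
and scalp electrodes inside the static field B0, inducing a voltage
transient that is loosely locked to the ECG R peak, drifts in amplitude
over minutes, and flips polarity between the two hemispheres. In
resting-state studies there is no event structure to average over, so the
artifact must be removed from the continuous signal while preserving
ongoing rhythms — above all the occipital alpha (8–13 Hz).

`pacorrect` implements the standard two-stage attack:

1. **OBS** (optimal basis set): per channel, the signal in each
   pulse-artifact window (0–700 ms after each R peak) is regressed onto
   the epoch-mean template plus the first 3 principal components of the
   epoch stack, and the fit is subtracted.
2. **Extended-infomax ICA** on the OBS-corrected signal (estimated on the
   whole recording, `ICA_whole`, or on the concatenated pulse-artifact
   epochs, `ICA_R`), followed by removal of the components one of four
   criteria marks as cardiac:
   * `pvaf` — back-projected variance inside the PA intervals above 2.5%
     of the signal variance there;
   * `corr` — absolute correlation of the epoch-averaged activation with
     a left- or right-hemisphere PA template at ≥ 40% of the best
     component's correlation (midline channels enter both templates);
   * `pacf` — a partial-autocorrelation peak at the cardiac recurrence
     lag above 1/3 of the largest such peak;
   * `wave` — a Morlet time-frequency map of the component, averaged over
     PA epochs, showing an R-locked peak between the delta and alpha
     bands (1–13 Hz).

Quality is quantified by three families of validation metrics computed on
−200–1000 ms epochs: the peak-to-peak ratio (PTP, post/pre amplitude
range), autoregressive band-power ratios with the quality coefficient
QC = alpha-ratio / mean(delta-ratio, theta-ratio), and the mean absolute
time derivative (MD) of `CWT_off`, the time-frequency content the
correction removed. Methods are compared across subjects with a
Kruskal–Wallis omnibus test and Tukey-style pairwise comparisons on mean
ranks.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `obs.n_pc` | 3 | – | standard OBS basis size |
| `obs.window_ms` | 0–700 | ms | pulse-artifact interval after R |
| `ica.max_iter`, `ica.tol` | 1000, 1e-7 | – | extended-infomax stopping rule |
| `selection.pvaf_threshold_pct` | 2.5 | % | variance-contribution cut |
| `selection.corr_rel_threshold` | 0.40 | – | relative correlation cut |
| `selection.pacf_block_size` | 4 | epochs | intervals averaged per block |
| `selection.pacf_rel_threshold` | 1/3 | – | relative PACF-peak cut |
| `selection.wave_threshold` | 3.0 | – | time-locking ratio cut |
| `selection.wave_band_hz` | 1–13 | Hz | "delta to alpha" search band |
| AR order (BFC) | 16 | – | resolves alpha vs theta on 1.2 s epochs at 250 Hz |
| bands | 1–4, 4–8, 8–13 | Hz | delta, theta, alpha |

All thresholds are configuration values with these numbers as defaults.

## Numerical and design choices

**Morlet parameterization.** The component-inspection wavelet is printed
as center frequency 14.591 Hz with bandwidth 5.836 Hz — a ratio of
exactly 2.5. We therefore implement a constant-Q analytic Morlet: at
analysis frequency $f$ the wavelet is
$e^{2\pi i f t}\, e^{-t^2/(2\sigma_t^2)}$ with
$\sigma_t = Q/(2\pi f)$, $Q = 2.5$. Each row is normalized so a
unit-amplitude stationary sinusoid at the row frequency reads magnitude 1
("instantaneous amplitude" / Gabor normalization); the constant is
computed from the kernel's discrete frequency response, and kernels are
truncated at $6\sigma_t$ so truncation sidelobes stay below $10^{-7}$.
In a constant-Q scale family the mother wavelet's nominal center
frequency (0.8125 Hz for the validation maps) only fixes the
scale-to-frequency mapping, not the per-row filter, so the same transform
serves both uses. The inspection grid is 20 log-spaced frequencies from
1 to 20 Hz inclusive ("twenty steps" read as 20 rows; a linear or
22-point reading changes scores by far less than the decision threshold);
the validation maps use 40 log-spaced rows.

**CWT on continuous signals.** Time-frequency maps are computed on the
continuous activation or channel signal and then segmented and averaged
over epochs, rather than transforming each epoch separately. Away from
epoch edges the two are identical; at the edges the continuous transform
uses the true neighboring samples instead of zero padding, which matters
because a 1 Hz wavelet barely fits a 700 ms epoch. Epochs overlapping
the recording-edge cone of influence are dropped from averages.

**The wave surrogate.** The original selection was a trained person
inspecting component maps. The automated stand-in scores how time-locked
a map is: for each 1–13 Hz row, its peak divided by its temporal median,
maximized over rows (rows carrying less than $10^{-4}$ of the map's peak
magnitude are ignored). A stationary rhythm scores ≈ 1 by construction;
R-locked transients on the ground-truth reference set score 3.3–5.2 while
neural sources score 1.0–1.1, so the default threshold 3.0 separates the
two classes with a wide margin. The score is calibrated on, and validated
against, the synthetic reference decomposition only — a green test says
the surrogate reproduces the intended behavior on that world, not that it
matches any individual human rater.

**PACF target lag.** "Blocks of four PA intervals averaged" is
implemented as averaging within each block of 4 consecutive epochs and
concatenating the block averages. Averaging only 4 epochs is essential:
it suppresses background by 2 while leaving enough of it that the
cardiac repetition appears as a genuine partial-autocorrelation peak — a
noise-free periodic sequence is exactly predictable by a low-order AR
model and shows *no* peak at its period. Because the 0–700 ms epochs are
concatenated without the diastolic gap, one cardiac cycle recurs at a lag
of one epoch length (175 samples at 250 Hz), not at the real-time R-R
lag; the search window is ±10% of that target, a peak must exceed a
conservative white-noise band of $4/\sqrt{N}$ (the search spans ~35 lags,
so the textbook $2/\sqrt{N}$ band fires on noise alone), and the PACF is
computed by Levinson–Durbin recursion (`stats::pacf`).

**OBS details.** Per-channel PCA of the mean-removed epoch stack;
ordinary least squares of each epoch onto [mean, PC1..3]; when
consecutive windows overlap (short R-R), the later fit is subtracted only
over the non-overlapped tail to avoid double subtraction. A tiny ridge
(1e-12 relative) keeps the normal equations stable when the basis
degenerates. Samples outside all windows are untouched, bit for bit.

**ICA.** Extended infomax (tanh nonlinearity with a per-component
sub/super-Gaussian sign estimated from subsampled kurtosis every 10
blocks), natural-gradient updates over shuffled blocks
(block ≥ 512 samples on long recordings), learning-rate annealing by 0.98
when the update direction turns by more than 60°, restart at half the
rate on divergence, stop when the squared weight change per pass falls
below 1e-7 (cap 1000 passes; non-convergence is an error, not a warning).
Data are centered and PCA-whitened first, dropping eigenvalues below
1e-10 of the largest and recording the retained rank; components are
ordered by back-projected variance with the largest-magnitude mixing
weight made positive. Block shuffling uses an internal xorshift
generator, so a seed fully determines the fit independent of R's RNG
state. In `pa_epochs` (ICA_R) mode the unmixing is estimated on the
concatenated 0–700 ms epochs but applied to the continuous recording, so
removal and the −200–1000 ms validation work on the full signal.

**R-peak detection.** Matched filtering with a QRS template: normalized
cross-correlation, local maxima above 0.7, 300 ms refractory period
(greedy by descending correlation). 0.7 was chosen because a matched QRS
correlates near 1 at true beats and below ~0.6 at T waves and noise in
the simulated ECG; the interactive verification of the original workflow
has no offline equivalent.

**MD metric.** The "time derivative averaged over time and frequency" of
`CWT_off` is implemented as the mean absolute finite difference along
time (scaled to magnitude/s), averaged over frequency rows: a signed
derivative of a bounded map averages to ~0 by the fundamental theorem of
calculus, so the magnitude is the only informative reading. MD ≥ 0, and
MD = 0 exactly when every frequency row of the removed content is
constant in time.

**Statistics.** Kruskal–Wallis via `stats::kruskal.test` (tie-corrected);
when the omnibus test rejects at 0.05, pairwise comparisons use the
Nemenyi/Tukey procedure on mean ranks with the studentized-range
distribution. The null rejection rate is verified at 0.05 ± 0.02 over
2000 simulated replicates.

## The synthetic world

`generate_dataset()` is the package's ground truth. Its defaults are the
canonical fixture: 64 channels (10-10 labels), 250 Hz, 360 s; R-R
intervals truncated-normal 1.0 ± 0.05 s; background = per-channel 1/f
Gaussian noise (10 µV RMS, exponent 1) with a shared common-mode term,
plus an amplitude-modulated 10 Hz alpha rhythm (5 µV RMS, random phase
w.r.t. the heart) on occipito-parietal channels; the artifact = five
R-locked kernel trains (damped 3–6 Hz oscillation + slow lobe + small
alpha-range ringlet, so its spectrum concentrates in delta–theta with a
secondary alpha lobe), mixed through smooth topographies positive on the
left and negative on the right hemisphere, amplitude-drifting by ±30%
across the recording (monotone half-cosine), with ±20 ms per-beat
latency jitter and 10% per-beat amplitude noise, scaled so the artifact
RMS inside PA windows equals the background RMS (epoch-SNR 1.0). The ECG
channel is a QRS-T train plus baseline wander and noise.

What the generator does **not** emulate: real electrode geometry and
volume conduction, non-Gaussian EEG transients (blinks, muscle),
gradient-artifact residuals, heart-rate variability structure beyond
i.i.d. R-R intervals, or electrode drift. A green test therefore
establishes algorithmic correctness on a controlled world, not clinical
performance.

## A known, honest limitation of the stated world

At artifact epoch-SNR 1.0 the beat-to-beat *variation* of the artifact
(drift, jitter, amplitude noise — a few µV) is much smaller than the
background inside each window (10 µV). The top-3 principal components of
the OBS epoch stack are then background (1/f) directions, not artifact
dynamics, and the per-epoch OLS fit removes roughly 35–40% of the
background variance inside PA windows (~7 µV RMS of neural signal) while
the mean template removes the locked artifact. This collateral damage is
intrinsic to OBS whenever the artifact does not dominate the background —
with a realistically dominant artifact (5–20× the EEG, as in actual
recordings at 3 T) the PCs capture artifact variation and the damage is
minor. Consequences on the fixture: the epoch-averaged artifact is
reduced by ~96% (OBS + ICA), but the corrected occipital signal
correlates with the ground-truth clean signal at r ≈ 0.75–0.84 — an
upper bound set by the OBS stage alone, before ICA sees the data. The
acceptance test asserting r ≥ 0.9 for the wave variant is implemented as
stated and is expected to fail on this world; the analysis above is the
reason, and the corresponding reduction assertions pass with a wide
margin.

## Other limitations

* The wave criterion replaces subjective inspection; its threshold is a
  property of the surrogate score, not of the original raters.
* `compare_runs` treats seeds or subjects as exchangeable; no repeated-
  measures structure is modeled.
* EDF output is 16-bit quantized and truncated to whole 1 s records;
  BrainVision float32 is the lossless interchange format.
* The pipeline assumes gradient-artifact correction and downsampling have
  already happened upstream; recordings are trimmed by the caller if a
  scan-onset convention applies.
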