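---
title: "Methods: Stockwell-transform deep-feature screening of phonocardiograms"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Stockwell-transform deep-feature screening of phonocardiograms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pcgst)
```

# The problem

Cardiac auscultation screening records heart sounds (phonocardiograms,
PCGs) at four valve listening points — aortic (AV), pulmonary (PV),
tricuspid (TV) and mitral (MV) — and asks two questions per patient:
does the patient have a murmur (Present / Absent, or Unknown when the
recordings are too poor to tell), and is the clinical outcome Normal or
Abnormal. Murmurs are turbulence noise gated into systole, and they live at
higher frequencies (roughly 100–300 Hz) than the S1/S2 heart sounds
(roughly 30–70 Hz), which is why a time–frequency representation separates
them well.

`pcgst` implements the complete screening pipeline: time–frequency
analysis with the discrete Stockwell transform, image conversion,
convolutional feature extraction, per-patient fusion across locations,
dimensionality reduction, class rebalancing, classification, and the
clinical scoring metrics. A synthetic cohort simulator generates labeled
PCG data with the same structure, so the entire pipeline is testable
without clinical recordings.

# The discrete Stockwell transform

For a signal $z[nT]$ of length $N$ sampled at $1/T$ Hz, the package first
takes the DFT with the $1/N$ forward normalization,

$$Z\!\left[\tfrac{k}{NT}\right] = \frac{1}{N}\sum_{n=0}^{N-1} z[nT]\,
  e^{-j2\pi kn/N},$$

so that $Z[0]$ is the signal mean. The Stockwell voice at frequency index
$n \ge 1$ is the inverse DFT (over $k$, at each output time $m$) of the
circularly shifted spectrum weighted by a frequency-dependent Gaussian:

$$S\!\left[mT, \tfrac{n}{NT}\right] = \sum_{k=0}^{N-1}
  Z\!\left[\tfrac{k+n}{NT}\right] e^{-2\pi^2 k^2 / n^2}\, e^{+j2\pi km/N}.$$

The Gaussian window $e^{-2\pi^2k^2/n^2}$ widens (in frequency) as $n$
grows, giving the transform its characteristic behaviour: long windows and
fine frequency resolution at low frequency, short windows and fine time
resolution at high frequency. Two conventions needed fixing where the
formulation leaves them open, and both are the standard choices for this
transform: the spectral shift $Z[k+n]$ wraps circularly (mod $N$), and the
$n = 0$ voice — where the Gaussian degenerates — is defined as the constant
signal mean (`st_dc_voice()`).

Two exact identities make the implementation cheap and testable:

* **Oracle equivalence.** Each FFT-computed voice equals the direct
  $O(N^2)$ double-sum evaluation to floating-point precision; the test
  suite checks every voice of random signals up to $N = 256$ against an
  independently written matrix-product oracle at $10^{-9}$.
* **Spectral collapse.** Averaging a voice over time recovers $Z[n]$
  exactly (only the $k=0$ term survives), checked at $10^{-10}$.

Numerical notes: all arithmetic is double precision, the FFT length is
exactly $N$ (no zero padding), and the Gaussian factor underflows below
double precision beyond $k \approx 1.42\,n$, so the windowed spectrum is
truncated there (error $< 10^{-17}$, far inside every stated tolerance).
When the time-decimation factor divides $N$, the decimated voice is
computed exactly as the short inverse DFT of the aliased (folded) windowed
spectrum — an identity, not an approximation, and tested as such.

`stockwell()` computes only the voices inside a frequency band, 20–350 Hz
by default: heart sounds and murmurs carry next to no usable energy above
350 Hz, and the band keeps the map small. On a preprocessed record
(12.5 s at 1000 Hz) the full-resolution default band holds 4126 voices of
12500 samples; since the map is destined for a fixed-size image, the
pipeline computes a decimated grid (`voice_step = 18`, `time_step = 10`,
about 230 × 1250) and lets bilinear resizing do the rest. The amplitude
map $|S| = \sqrt{\mathrm{Re}^2 + \mathrm{Im}^2}$ is the feature-extraction
input; because images are min–max normalized downstream, the DFT
normalization convention has no effect on the features.

# Preprocessing

Every recording is (1) resampled to 1000 Hz — a zero-phase 63-tap Hamming
FIR low-pass at 90% of the target Nyquist, then linear interpolation onto
the target grid, output length exactly `round(N * target_fs / fs)`; (2)
fixed to 12.5 s — longer records truncated, shorter records tiled
end-to-end with no crossfade; (3) amplitude-normalized, by default
symmetric min–max into $[-1, 1]$ ("normalized units"). The order —
resample, then fix duration, then normalize — is deliberate: tiling before
the anti-alias filter would push the tiling discontinuities through the
filter twice. A z-score mode is available; whether normalization happens
before or after rate reduction is immaterial for min–max scaling, and the
choice is config-exposed rather than hidden.

# Feature extraction and fusion

The amplitude map is min–max scaled to $[0,1]$, bilinearly resized
(align-corners convention: resizing to the map's own size is the
identity), oriented with low frequencies at the bottom row, and replicated
to three channels. An AlexNet-shaped convolutional stack then produces a
feature vector: conv1 with 96 filters of 11×11 and stride 4 plus ReLU,
3×3/2 max-pools, deeper 5×5 and 3×3 convolutions, and fully connected
layers; the activations of the first FC layer are the features (width
4096 for the `"alexnet"` preset).

The backbone is deliberately a pluggable inference-only contract. Trained
weights can be loaded from a file; the default for simulation studies is a
seeded He-normal random initialization, i.e. a structured random
projection. Random-projection convolutional features preserve the class
structure of inputs whose classes differ in spatial energy distribution —
exactly the murmur signature on a time–frequency map — and the end-to-end
tests assert this empirically (held-out weighted accuracy far above
chance). Training loops are out of scope.

Two presets exist: `"alexnet"` (227×227×3 input, 4096-d features) and
`"small"` (127×127×3, identical conv1 geometry and pooling, 512-d
features). The package's own simulation studies and tests use `"small"`:
at roughly 20× less compute per image it keeps a 200-patient,
~700-recording study in the minutes range on one core, and the claims the
studies make (class separability, SNR response, determinism) do not depend
on feature width.

Per patient, location vectors are concatenated in the fixed order AV, PV,
TV, MV into one row of length `4 * dim`. Several recordings at one
location are averaged elementwise; a missing location contributes zeros
and a mask flag. Fixed width and fixed order make the rows classifier
ready regardless of which locations were recorded, and fusion is invariant
to the order in which locations are supplied.

# Reduction, balancing, classification

**RFE** ranks features by the squared weights of a linear SVM
(one-vs-rest sum for the 3-class task), drops the worst, and refits until
`k = 120` remain — 120 being the operating point that balances accuracy
against dimensionality in this pipeline. Features are standardized before
ranking (unscaled weight magnitudes are not comparable). Strict
one-at-a-time elimination from thousands of features is needlessly
expensive, so by default each round removes 10% of survivors until within
$2k$, then one at a time; with well-separated importances the coarse and
exact schedules select identical sets, and the tests construct exactly
that situation. **PCA** (via `prcomp`) is the variance-based alternative;
**none** passes the fused vector straight through.

**SMOTE** rebalances training rows only: the majority class is first
down-sampled without replacement (default: keep 80%), then each minority
class is grown with interpolated synthetic points
$x_i + u\,(x_{nn} - x_i)$, $u \sim U(0,1)$, between $k=5$ same-class
nearest neighbours, until classes reach parity. The combination of
down- and up-sampling follows the pipeline's stated strategy; the exact
proportions are not recoverable from its description, so they are
explicit, logged configuration with the values above as defaults.

Classifiers are thin, seeded wrappers: linear SVM (`e1071`), random
forest (`ranger`, single-threaded for byte-reproducibility), gradient
boosting (`xgboost`). The operating combinations are RFE + RF for the
murmur task and RFE + linear SVM for the outcome task. Splits are
stratified at the patient level (80/20 by default): recordings of one
patient never straddle the split, scaler statistics come from training
rows only and are frozen into the model, and balancing and reduction see
training rows only — the determinism and no-leakage tests assert all
three.

# Scoring

Murmur detection is scored with the weighted accuracy
$$\mathrm{WAcc} = \frac{5N_{PP} + 3N_{UU} + N_{AA}}
 {5\sum_i N_{iP} + 3\sum_i N_{iU} + \sum_i N_{iA}},$$
first index prediction, second expert label: missing a murmur is five
times worse than mislabelling a healthy patient. Outcome screening is
scored with the clinical cost
$$c = \tfrac{1}{N}\bigl(35N + 397M - 1718\,M^2/N + 11296\,M^4/N^3
 + 10000\,TP + 50000\,FN\bigr),$$
where $M$ counts patients predicted Abnormal, $TP$ correctly treated and
$FN$ missed patients; lower is better, and an all-Normal prediction on an
all-Normal cohort costs exactly 35 per patient. Both are verified against
independently written literal expressions on thousands of random count
tuples. Secondary metrics are accuracy, sensitivity, specificity, F-score
and AUC (rank method, ties counted half, equal to brute-force pairwise
counting and cross-checked against `pROC`); multi-class summaries are
one-vs-rest macro-averages, with per-class values also reported. For the
outcome task a binary weighted accuracy (weight 5 on Abnormal) is provided
as the two-class reading of the murmur score.

# The synthetic cohort simulator

`simulate_recording()` builds a heart-sound cycle as Gaussian-enveloped
tone bursts: S1 near 30–45 Hz, S2 near 50–70 Hz placed 30% of the cycle
after S1, over a broadband noise floor 30 dB below the S1 peak. A murmur
is band-limited (100–300 Hz) Gaussian noise gated into systole by a
raised-cosine window, scaled by a per-location gain (PV loudest by
default, reflecting the location-varying intensity of real murmurs) and a
26 dB default SNR over the noise floor. Cohort defaults mirror the
screening population the pipeline targets: 4000 Hz recordings of 5–65 s,
heart rates 70–140 bpm, murmur prevalence 30%, and 10% "Unknown" patients
simulated as quality-degraded recordings (noise floor raised to −8 dB) —
Unknown in the source labels marks low-quality records, and that is what
the simulator reproduces. About 30% of patients drop one or two
auscultation locations to exercise missing-location handling. Abnormal
outcome (prevalence 50%, independent of the murmur label) is expressed as
a louder, 15 Hz higher S2 — a deliberately different acoustic signature,
so that outcome classification is learnable while murmur injection remains
strictly equivalent to the Present label. Signals are quantized to the
16-bit grid at generation so WAV round-trips are bit-exact.

What the simulator does *not* model: valve mechanics, diastolic murmur
taxonomy, respiration and motion artifacts, sensor variety, or the
correlation structure of real clinical labels. Passing tests on this
cohort therefore demonstrate that the pipeline's machinery — transform,
features, fusion, reduction, balancing, scoring, reproducibility — works
and recovers planted class structure; they are not evidence of clinical
performance, which can only be measured on real data.

# Problem sizes and reproducibility

The simulation studies run 200-patient cohorts (about 700 recordings) with
the `"small"` backbone, RFE to 120 features and a random forest: one full
study takes a few minutes on a single core. Smaller cohorts with short
(5–15 s) recordings back the unit tests. Every stochastic stage — cohort
sampling, backbone initialization, majority down-sampling, SMOTE
interpolation, splitting, forest growth — draws from an explicit seed
through an RNG-state-preserving wrapper, and identical seed + config +
data yields byte-identical metric reports across processes; this is
asserted by test, not assumed.

# Known limitations

* The backbone is untrained by default; with pretrained weights the
  feature quality on real data would differ substantially.
* Signal-quality assessment and heart-sound segmentation are out of
  scope; the Unknown class is handled only through training labels.
* The simulator's Abnormal signature is a convenience for end-to-end
  validation, not cardiology.
* `read_wav()` supports the 16-bit mono PCM subset of WAV — the format
  the simulator emits and screening datasets use.
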