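---
title: "Methods: GASF imaging and domain-generalized classification of physiological signals"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GASF imaging and domain-generalized classification of physiological signals}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Wearable sensors produce multichannel physiological recordings — electrodermal
activity, blood volume pulse, skin temperature, respiration — sampled at
channel-specific rates, together with a per-instant emotion label. Two
properties make classifying such data hard. First, raw series are long and
high-rate, and the discriminative information is largely spectral (arousal
changes the dominant frequency content of EDA and BVP more reliably than it
changes instantaneous amplitudes). Second, physiological signals are
nonstationary: the distribution of a subject's signal drifts over a recording,
so a model trained on the chronologically early part of a recording faces
*temporal covariate shift* (TCS) on the later part. Randomly shuffled
train/test splits hide this; chronological splits expose it.

`physiogasf` implements a pipeline that addresses both: spectral feature
pre-extraction condenses each channel; Gramian angular summation field (GASF)
imaging turns feature windows into image stacks whose textures encode temporal
correlation; a dual-stream 3D-convolutional residual network classifies them;
and a domain-generalization stage — KMeans++ segmentation of same-class
training samples into maximally dissimilar "domains" plus a maximum mean
discrepancy (MMD) alignment loss — pushes the encoder toward features that
survive distribution drift.

## Feature pre-extraction

Each channel is cut into `T` contiguous subseries of `subseries_duration`
seconds (default 1 s, so a subseries holds `sampling_rate` samples — a natural
DFT length; a trailing remainder is dropped). Per subseries seven features are
computed:

* mean and sample standard deviation (denominator `N - 1`);
* from the single-segment windowed periodogram
  `P(j) = |Σ_k z(k) x_k e^{-i2πjk/N}|² / (Z N)`, `Z = mean(z²)`, with a
  Hamming window `z(k) = 0.54 - 0.46 cos(2πk/(N-1))` by default (the
  rectangular window recovers the plain periodogram and satisfies Parseval's
  identity over all `N` bins): spectral entropy (base-2, `0·log 0 := 0`),
  gravity frequency (the PSD-weighted centroid of the bin frequencies),
  frequency mean, frequency standard deviation, and root-mean-square
  frequency.

Bins `j = 0..⌊N/2⌋` (DC through Nyquist) are retained. Internally the DFT uses
the conventional `j = 0..N-1` indexing; a 1-based `j = 1..N` convention is
equivalent via the periodicity `j = N ↔ j = 0`. Two deliberate literalisms:
the *frequency mean* is the arithmetic mean of the retained PSD values with a
`1/N` prefactor — a power average, not a frequency; and the centroid-style
features weight the *bin frequency in Hz*. Both follow the feature set as
defined; by construction `x_rmsf² = x_fstd² + x_gf²`, which the test-suite
asserts. The `T × 7O` feature matrix is ordered channel-major (channel block,
then mean, std, se, gf, fmean, fstd, rmsf), and each row carries the label at
the end instant of its subseries.

Features are z-scored per column before imaging. The statistics — like the
global min/max table below — are frozen on the training rows only, so later
(validation/test) rows never leak into the scaling.

## GASF imaging

Sliding windows of `W` feature rows (step 1, so `n = T - W + 1` samples) take
the label of their **last** row — the most recent instant, which is the
quantity a real-time classifier must report. Each of the `7O` columns of a
window is rescaled to `[-1, 1]` and mapped to polar angles `φ = arccos(q̃)`;
the GASF plane is `G[j,k] = cos(φ_j + φ_k)`, equivalently
`q̃ q̃ᵀ - √(1-q̃²) √(1-q̃²)ᵀ`. `G` is symmetric, bounded, and its diagonal
`2q̃² - 1` retains the (unsigned) values themselves, so the image preserves
both the series and its pairwise temporal structure.

Rescaling comes in two flavours, and the pipeline uses both:

* **local** (window min/max): invariant to positive affine transforms, so it
  captures shape but discards level — `[1..5]` and `[101..105]` map to the
  same `[-1, -0.5, 0, 0.5, 1]`;
* **global** (feature-wide min/max from the training series): preserves the
  window's absolute level, at the cost of flattening local detail when the
  global range is wide.

The paired `W × W × 7O` local and global stacks feed the two streams of the
encoder. Design points: a constant window rescales to all zeros (the interval
midpoint; its GASF plane is constantly `-1`), arccos inputs are clipped with a
1e-9 tolerance for floating-point overshoot, and global-rescaled values
outside the training range (possible at inference) are clipped to `[-1, 1]`.

## The residual feature encoder

Each stream is a small 3D ResNet: input layer (3×3×3 convolution, batch
normalization, ReLU, 2×2×2 max pooling) followed by 8 residual blocks with
downsampling (stride-2 first convolution, 1×1×1 stride-2 projection skip) at
blocks 3, 5 and 7, global average pooling, and a linear layer to a per-stream
embedding. The two embeddings are concatenated and classified through dropout
and a linear layer. The `7O` feature planes form the **depth axis** of a
single-channel 3D volume, so kernels mix adjacent feature planes as well as
spatial (temporal × temporal) positions — with the alternative layout (planes
as channels) the third kernel dimension would be meaningless.

Choices the architecture description leaves open, fixed here: channel widths
start at `base_width` (default 16) and double at each downsampling block;
embeddings default to 128 per stream; dropout (rate 0.2) sits between the
concatenation and the classifier; the two streams have independent weights;
weights use Kaiming (He) normal initialization; convolutions carry no bias
(batch normalization absorbs it; a conv bias before BN would receive an
identically zero gradient). Axes that have collapsed to size 1 get 1-tap
kernels and stride 1, so every remaining weight can touch data and spatial
sizes never fall below 1; pooling likewise skips size-1 axes. `W ≥ 2` is
required.

The network, including the backward pass, is implemented in this package
(Rcpp/RcppArmadillo im2col+GEMM kernels for the 3D convolutions and pooling,
R for the rest); analytic gradients are verified against central differences
in the test-suite.

One numerical subtlety: batch-normalization running statistics accumulated
*during* training lag the final weights, which distorts the deterministic
evaluation-mode forward pass badly on small data. `train_rbfe()` therefore
finishes with a recalibration pass that recomputes the running statistics
over the training set under the final weights (equal-weight chunk averaging).

## Domain segmentation and alignment

Chronological drift means same-class training samples are not identically
distributed. Rather than segmenting domains by subject, the pipeline
*discovers* maximally dissimilar same-class groups: each window is summarized
by a fixed catalog of 13 statistics per feature column (mean, variance,
skewness, kurtosis, min, max, median, absolute energy, mean absolute change,
lag-1..3 autocorrelation, count above mean; undefined values are dropped
consistently across samples), features irrelevant to the labels are removed
by pairwise Mann–Whitney tests (worst-case p per feature,
Benjamini–Yekutieli control at 0.05, with a top-k fallback), and the z-scored
survivors are clustered per class with KMeans++ (`k_init` default 4).

Small clusters are then merged: while the smallest cluster is below the stop
threshold and more than one remains, it merges into its nearest same-class
neighbour — by Euclidean centroid distance when its size is below `Δ₁`
(default 50), by the Gaussian-kernel MMD

`MMD(U,V) = mean k(u,u') + mean k(v,v') - 2 mean k(u,v)`,
`k = exp(-‖·‖²/2σ²)`

when its size is in `[Δ₁, Δ₂)` (default Δ₂ = 300; σ from the median pairwise
distance heuristic). The published procedure states that merging prevents
overly small clusters but no explicit stop rule; this implementation stops
when the smallest cluster reaches `Δ₂` (configurable to `Δ₁`), since `Δ₂`
otherwise only bounds the MMD regime. Segmentation is made order-invariant by
canonicalizing the within-class row order before seeding, and deterministic
under the seed.

During training, an auxiliary loss aligns the per-class domains in embedding
space: for each class with ≥ 2 domains represented in the batch, the MMD
distances over all unordered domain pairs are averaged, and the loss is the
mean over such classes (the pair-mean keeps the loss scale stable in the
domain count). Batches are stratified round-robin over (class, domain) cells
so pairs are non-degenerate. The total loss is

`L = L_cls + λ·L_dis + η·‖W‖²`

with cross-entropy classification loss, λ = 0.01 and η = 1e-6 by default, and
the L2 penalty over convolution/linear weights only. The embedding aligned is
the pre-classifier concatenation (the standard penultimate representation);
the alignment σ is recomputed per batch by the median heuristic. Adam
minimizes `L`. With λ = η = 0 training reduces exactly to plain cross-entropy,
which the tests assert. Note that the dropout 0.2, batch size 1024, window
sizes 6 (and 11), and thresholds 50/300 are documented presets of the method;
the learning rate (1e-3) and trade-off weights are conventional defaults, as
the printed values of the source settings contain evident exponent typos.

## Evaluation protocols

* `chronological_split()` orders windows by start index and splits 8:1:1
  (validation/test sizes floored, remainder to training). Because windows
  overlap, boundary windows share feature rows with the neighbouring
  partition; they are counted and flagged (`"boundary_overlap"` attribute)
  rather than silently dropped. The split is per recording/subject.
* `timestep_eval()` splits windows into 16 chronological parts, trains on
  part 1 (all frozen statistics computed there) and reports accuracy on parts
  2–16 as time steps 1–15 — the TCS stress protocol.
* `evaluate_model()` reports accuracy, macro-F1 (weighted variant available)
  and the C × C confusion matrix with rows as the true class.

## The synthetic generator

No public physiological dataset ships with this package; every claim is
exercised on synthetic recordings built to emulate the *statistical* structure
the pipeline targets — not waveform morphology. Each channel is
`baseline + amplitude·sin(phase) + N(0, noise²)` with a class-dependent
dominant frequency (classes occupy contiguous label blocks); drift adds a
linear baseline shift and a frequency chirp (phase is integrated, so the chirp
is clean); planted regimes shift baseline/frequency/amplitude in contiguous
segments. Three bundles fix the study conditions:

* `easy-stationary` — 2 classes × 2 channels (32/16 Hz), dominant
  frequencies (2, 1) vs (6, 4) Hz, noise sd 0.3, 60 s label blocks, 840 s.
  Well separated; the end-to-end smoke condition.
* `drifting-tcs` — same classes, 1920 s, noise sd 0.2, baseline drift +0.5
  and +15 % frequency drift over the recording, plus an amplitude regime
  (×1.4) switching at the midpoint. The drift magnitude was chosen so that
  the 16-part protocol shows a gradual, predominantly monotone accuracy
  decline while an otherwise identical stationary control stays flat; the
  recording is long enough that one part (~120 windows) supports training at
  all. The amplitude regime plants genuine within-class domain structure
  inside a chronological training span — without it, domain segmentation of
  an early training segment collapses to one domain per class and the
  alignment loss has nothing to align.
* `two-regime` — stationary classes, 960 s, two contiguous regimes with
  baseline +3, frequency ×1.6, amplitude ×1.5 — far enough apart
  (between-regime distance ≫ within-regime spread) that segmentation should
  recover them; thresholds scaled to the bundle (Δ₁ = 50, Δ₂ = 150).

Because label blocks alternate classes, windows straddling a block boundary
are genuinely ambiguous (the window mixes classes but carries the last row's
label); block lengths were chosen to keep such windows rare. What passing
tests on these bundles shows is that the machinery — features, imaging,
encoder, segmentation, alignment, protocols — behaves as specified under
controlled spectral class structure and controlled drift. It does not certify
accuracy on real wearable data, where morphology, artifacts, label noise and
subject heterogeneity matter.

## Problem sizes and numerical choices

The test-suite and worked examples run the full pipeline at desk scale: the
training runs use `base_width` 4–8, embeddings 16–32, batches 64–128 and ≤ 30
epochs on recordings of 840–1920 s, sizes at which a run takes tens of
seconds to a few minutes on one CPU while still exercising every stage at
realistic window counts (hundreds to ~2000). Other fixed numerics: GASF
arccos clipping tolerance 1e-9; BN ε = 1e-5, momentum 0.1 (biased batch
variance); Adam β = (0.9, 0.999), ε = 1e-8; cross-entropy probability floor
1e-12; degenerate (constant) windows rescale to zeros; KMeans++ uses Lloyd
iterations from D²-sampled seeds, dropping empty clusters; a class with fewer
than `max(2, Δ₁)` samples forms a single domain.

## Known limitations

* Batch training is full-backprop on CPU; recordings beyond a few thousand
  windows or models beyond `base_width` ≈ 16 become slow.
* The per-stream linear embedding size and channel widths are conventions,
  not reproductions — the source architecture leaves them unstated.
* Multi-rate channels are subseries-split independently (never resampled);
  whether the original method resampled is unknown.
* No artifact removal or filtering beyond short-gap interpolation; inputs are
  assumed clean.
* `stat_features()` uses a pinned 13-statistic catalog rather than a
  tsfresh-scale battery; an external extractor can be plugged in behind the
  same `pg_stat_table` interface.
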