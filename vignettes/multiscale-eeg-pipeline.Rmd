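---
title: "Multi-scale kernel CNNs on topographic EEG features: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-scale kernel CNNs on topographic EEG features: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem and the model

`msceeg` classifies affective state (the valence and arousal dimensions of
emotion, self-rated on a 1–9 scale) from multichannel scalp EEG. The input is
a trial: 32 electrodes sampled at 128 Hz for 63 s — a 3 s pre-stimulus
baseline followed by 60 s of stimulus. Ratings are binarized at 5 (a rating
of exactly 5 counts as *low*; the split convention is configurable), giving
binary arousal, binary valence, and their four-way cross product
HAHV/HALV/LAHV/LALV as classification tasks.

The pipeline has four stages.

**1. Band decomposition.** Each channel is decomposed into Theta (4–8 Hz),
Alpha (8–14 Hz), Beta (14–31 Hz) and Gamma (31–50 Hz) time signals with
order-30 Butterworth band-passes. Delta is omitted: preprocessed recordings
of this kind are already high-passed above 4 Hz. The high order makes the
transition bands extremely narrow, so the band signals overlap only
trivially at the stated edges (half-power at exactly 8, 14, 31 Hz).

**2. Segmentation.** The baseline is discarded and the 60 s stimulus period
is cut into n = 10 contiguous, non-overlapping 6 s segments (768 samples).
Every segment inherits its trial's label and is treated as an independent
sample, so 32 subjects × 40 trials × 10 segments = 12,800 samples.

**3. Time-domain features on a scalp map.** For every (segment, channel,
band) six statistics are computed:

* differential entropy $\mathrm{DE} = \tfrac12\ln(2\pi e\hat\sigma^2)$
  (Gaussian closed form, nats), with $\hat\sigma^2$ the biased ($1/n$)
  sample variance,
* mean $\bar\mu$,
* mean first difference $\bar\mu_1 = \frac{1}{n-1}\sum_i (x_{i+1}-x_i)$,
* mean second difference $\bar\mu_2 = \frac{1}{n-2}\sum_i (x_{i+2}-x_i)$,
* standard deviation $\sigma$ and variance $\sigma^2$ (biased).

Features are min-max normalized to $[0,1]$ within each trial, then the 32
per-channel values of each (band, feature) pair are placed on a 9×9 grid at
the electrode's 10–20 scalp position (the 49 empty cells are exactly zero),
the four band grids are tiled 2×2 into an 18×18 matrix (Theta top-left,
Alpha top-right, Beta bottom-left, Gamma bottom-right), and the six feature
matrices are stacked along the depth axis: one sample is an 18×18×6 tensor.
Single-band or raw (unfiltered) arms give 9×9×k tensors, and a two-band arm
tiles 1×2 into 9×18. The tensor makes both spatial channel adjacency and
band adjacency visible to 2-D convolutions.

**4. The multi-scale kernel CNN.** Four convolution blocks of 16, 32, 64 and
128 output channels share one structure: parallel same-padded convolutions
with kernel sizes 5×5 and 7×7 (configurable among {3,5,7}), channel-wise
concatenation, a 1×1 convolution fusing the branches back to the block
width, batch normalization, ReLU. There is *no pooling*: on an 18×18 input
pooling would destroy most of the map, so spatial size is preserved end to
end and a single fully connected layer maps the flattened final block to
class logits. The parallel kernels are the point: adjacent electrodes
correlate strongly (small kernels capture local patterns), while remote
electrode pairs and cross-band relations can correlate positively,
negatively or not at all (large kernels capture those global patterns).

**Training protocol.** Adam, softmax cross-entropy (the two-logit softmax
head on binary tasks is binary cross-entropy in an equivalent
parameterization), initial learning rate 0.001 annealed by a cosine schedule
to one tenth at the last epoch,
$\mathrm{lr}(e)=\mathrm{lr}_{\min}+\tfrac12(\mathrm{lr}_0-\mathrm{lr}_{\min})
(1+\cos\frac{\pi e}{E-1})$, 150 epochs, batch size 640, and 10-fold
cross-validation with folds drawn at random over all segments; the reported
figure is the mean of the ten fold accuracies.

# Synthetic data: what it emulates and what it does not

Real recordings of this kind (e.g. DEAP) are licence-gated, so the package
ships a generator that reproduces exactly the statistical structure the
pipeline exploits, and nothing else:

* **band-limited oscillations** in the four bands, synthesized by the
  random-phase spectral method (unit-magnitude Fourier bins with uniform
  phases inside the band) — deliberately independent of the Butterworth
  filter bank so filter tests are not circular;
* **1/f^α background noise** (default α = 1);
* **spatial correlation**: each band field is a mix
  $w\,v + (1-w)\,u$ of a shared regional source $v$ (the base field averaged
  over each electrode's grid neighbourhood) and per-electrode noise $u$,
  with `spatial_smoothness` $w \in [0,1]$ (default 0.7), so grid-adjacent
  electrodes correlate strongly and remote ones do not;
* **a class-coded power modulation** in Beta and Gamma on a frontal
  electrode group (F3, F4, Fz, FC1, FC2): amplitude × (1 + e) for the high
  class and × (1 − 0.5 e) for the low class, with `effect_size` e. The
  placement reflects where band power is most informative for emotional
  state; at e = 0 the signal is label-independent by construction.

Ratings are drawn consistently with the injected class (high → uniform
(5, 9], low → uniform [1, 5]); classes are balanced within subject. One
global seed derives per-subject and per-trial streams, so any subset
regenerates identically regardless of generation order.

Two deliberate non-features matter for interpreting results. First, band
amplitudes are deterministic given the configuration — trials differ only in
their noise realization. This means a null dataset (e = 0) carries no
trial-level fingerprint a classifier could memorize, which keeps the
chance-level check honest despite segment-level cross-validation (below).
Second, nothing physiological is modelled — no event-related potentials, eye
blinks, electrode drift or inter-subject variability. Passing the label
recovery check therefore demonstrates that the pipeline's plumbing,
features, tensors and optimizer work end to end; it says nothing about
accuracy on real EEG.

# Numerical and design choices

**Filter realization.** An order-30 band-pass has 60 poles; a single
transfer-function polynomial of that order is numerically meaningless in
double precision. The design therefore goes analog prototype → band-pass
transform → bilinear transform with prewarping (via the `signal` package's
s-plane machinery), and the digital poles are paired into 30 cascaded
biquads (second-order sections), each normalized to unit gain at the band's
geometric centre. Stability is asserted at design time (all pole moduli
< 1).

**Zero-phase filtering.** Filters are applied forward and backward by
default, squaring the magnitude response and cancelling the phase. The
time-domain features (first/second differences especially) are sensitive to
waveform timing, and a causal order-30 filter would delay each band by a
different amount; zero-phase application avoids any band-dependent
misalignment. Single-pass causal filtering is available
(`zero_phase = FALSE`). Edge transients are controlled by odd-reflection
padding of about three cascade group delays (estimated from the slowest
pole's decay constant), then trimmed.

**Degenerate inputs.** A constant segment has no finite differential
entropy; it is floored at the DE of the smallest representable positive
variance, with a warning. A normalization group with equal minimum and
maximum is set to 0, with a warning. Ratings exactly at the threshold are
*low* (strict inequality for *high*).

**Normalization grouping.** "Min-max within the trial" leaves open what to
pool. The default pools channels and segments separately per (band, feature)
pair: feature types with different physical units are never mixed, while the
spatial pattern across electrodes — what the CNN reads — is preserved up to
one affine map per band and feature. Global-per-trial and per-channel
groupings are available as options.

**Signed differences.** The first/second difference features are implemented
exactly as defined (signed), which telescopes to
$(x_n - x_1)/(n-1)$ and $(x_n + x_{n-1} - x_2 - x_1)/(n-2)$. The rectified
variant $\frac{1}{n-1}\sum|x_{i+1}-x_i|$ common in the feature-extraction
literature is available via `absolute = TRUE`.

**Start-shift ablation and `truncate_tail`.** Shifting the segmentation
start by up to 5 s cannot coexist with 10 × 6 s inside a 63 s recording.
With `truncate_tail = TRUE` trailing segments that overrun the recording are
dropped (9 segments at shifts ≥ 3 s); with the default `FALSE` the overflow
is an error that names the missing sample count.

**Segment-level cross-validation leaks trial identity.** Random folds over
segments put segments of the same trial in both train and validation sets;
since segments inherit trial labels, correlated trial-level structure
inflates accuracy relative to a subject- or trial-grouped split. The scheme
is replicated as the package's default because it is the protocol the
architecture was designed under, but `make_folds(group = )` and
`run_cross_validation(group = )` provide leakage-free evaluation. On the
synthetic data the point is moot by construction (no trial fingerprints; see
above).

**Model details left open by the architecture sketch.** Same-padding with
zero fill (required to reach the FC head at 18×18 with no pooling); each
parallel branch emits the full block width before concatenation, so the 1×1
fusion reduces |kernels|·C → C; batch normalization sits after the fusion
only; convolutions carry biases; weights are variance-scaling (fan-in)
Gaussian, seed-controlled; batch-norm running statistics (momentum 0.1) are
frozen at evaluation; the FC flatten order is channel-fastest, fixed for
reproducibility.

**The DEAP-layout container.** Subject files are RDS serializations of
`list(data = 40×40×8064, labels = 40×4)` — the documented per-subject layout
of the DEAP preprocessed release, with EEG in channels 1–32. The synthetic
writer emits the same layout, so `load_deap_subject()` is the single
ingestion path. The upstream release's pickle/MAT dialects are out of scope
for this R stack; converting one subject to RDS is a few lines of Python
(`scipy.io` / `pickle` → `data`, `labels`).

# Desk-scale validation sizes

The test suite and the acceptance script validate the pipeline at sizes a
single CPU handles comfortably; these are the package's reference choices,
not tuned values:

* *cardinality*: the full 32 × 40 synthetic dataset, raw (unfiltered) arm,
  must yield exactly 12,800 samples;
* *label recovery*: 4 subjects × 40 trials (1,600 segments), Beta+Gamma
  tensor arm (9×18×6 — the bands that carry the injected effect), one
  multi-scale block of 8 channels with kernels {5, 7}, 20 epochs, batch 64,
  10-fold CV. At `effect_size = 1.5` this must reach ≥ 90% mean accuracy; at
  `effect_size = 0` it must sit at 50% ± 5%. The reduced block stack keeps
  ten independent trainings tractable on one core; the class signal is
  linearly separable by design, so recovering it does not require the full
  16–32–64–128 stack;
* *shift robustness*: the same reduced protocol at 6 epochs under start
  offsets {0, 1, 2} s (with `truncate_tail`) must vary by < 3 percentage
  points.

Published headline accuracies for this family of models are computed on the
licence-gated DEAP recordings themselves and are therefore not reproduced by
this package's checks; the synthetic checks validate mechanism, not
benchmark numbers.

# Known limitations

* The engine is CPU-only and double precision; the full default
  architecture at the full 12,800-sample protocol is compute-hungry in this
  setting (it exists and trains, but expect hours, not minutes).
* Binary tasks use a two-logit softmax rather than a one-logit sigmoid;
  the losses are equivalent up to parameterization, but per-logit weight
  statistics differ from a sigmoid implementation.
* The synthetic four-class task is degenerate (arousal and valence encode
  the same injected bit), so four-class accuracy is only meaningful on real
  data.
* `pearson_correlation_map()` reports 0 with a warning for constant
  channels, where the correlation is undefined.
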