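---
title: "PDFuseNet: models, parameters and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PDFuseNet: models, parameters and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

PDFuseNet implements a severity-grading pipeline for Parkinson's disease
brain slices: fused-image preprocessing, a pyramid channel-attention feature
network (PCFAN), a compact MobileNetV3-style classifier, the Improved Dwarf
Mongoose Optimization (IDMO) metaheuristic for hyperparameter tuning, and a
one-vs-rest diagnostic metric suite. Because the clinical image collections
this task is usually studied on are access-controlled, the package includes
a synthetic phantom generator and validates the whole pipeline on it. This
vignette records the models, their tunable parameters, the numerical
choices, and what the synthetic validation does and does not establish.

## The synthetic phantoms

`generatePhantom()` draws a 2-D grayscale slice (default 128×128, unit
intensity range) containing an elliptical brain (tissue level 0.55) on a
dark background (0), a bright cortical band (0.85) whose thickness shrinks
with severity (12%, 9%, 6% of the brain semi-axis for mild, moderate,
severe), and paired dark lateral ventricles (0.12) whose semi-axes scale
with severity (1.0, 1.4, 1.8). On top of the geometry sit a smoothed
Gaussian texture field inside the brain (sd 0.04), a multiplicative linear
illumination gradient with random orientation (amplitude 0.3, admissible
range [0, 0.6]) and additive Gaussian pixel noise (sd 0.03), after which
intensities are clipped to [0, 1]. `generateDataset()` adds per-image
log-normal jitter (sd 0.06) to the ventricle scale and cortical thickness so
the class distributions overlap, and splits each class with
`round(splitFraction * nPerClass)` training images (default 0.8; 0.7 is the
other conventional preset).

Two deliberate choices keep the downstream validation honest. First, the
class signal is *geometric* — ventricle area and cortical thinning — not a
mean-intensity shift, so intensity-space preprocessing can neither destroy
nor fabricate it. Second, the signal is strong enough that a threshold rule
on the true ventricle-mask area already exceeds 80% accuracy; the end-to-end
bar for the trained classifier (macro accuracy at least 0.90) is calibrated
against this separability, not against any clinical benchmark. The phantoms
have no 3-D anatomy, no Rician noise model (noise is additive Gaussian by
default) and no radiological realism; passing tests on them demonstrates
that the pipeline's machinery works and can learn a morphological signal,
nothing more.

## Fusion preprocessing

Each image is preprocessed into a single fused slice from two copies.

**Contrast enhancement.** The enhanced image is the per-pixel convex
combination `R = W∘P + (1−W)∘g(P,k)`. The weight map is
`W = smooth(P)^μ` with a Gaussian of σ = 5 px and μ = 0.5 — the literature
this construction follows names only the goal (weight well-exposed pixels),
so the smoothed-luminance power law is our concrete choice and both σ and μ
are config fields. The brightness transform is the beta–gamma
camera-response form `g(P,k) = exp(b(1−kᵃ))·P^(kᵃ)` with a = 0.3293 and
b = 1.158, the constants most often printed for this enhancement family. Note
that the negative-exponent parameterization (a = −0.3293, b = 1.1258) is
also in circulation; with the positive constant, `g` darkens rather than
brightens for k > 1, the entropy criterion then selects k = 1 on typical
dark-background slices and the enhancement approaches the identity. Both
parameterizations are reachable through `fusionConfig()`; the default
follows the printed constants.

The exposure ratio k maximizes the Shannon entropy (256-bin histogram) of
`g(Q,k)` over the underexposed pixels `Q = {P : W < 0.5}` within k ∈ [1, 8],
by a 0.1-step coarse grid refined to a 10⁻³ grid around the coarse
maximizer, ties resolved toward the smallest k; if no pixel is underexposed,
k = 1. Entropy of a quantized histogram is piecewise constant in k, so an
argmax is only defined up to plateaus — the smallest-k tie-break makes it
deterministic.

**Mean filter.** Printed descriptions of this denoising step vary and are
often typographically garbled; it is implemented as the standard
box mean over an odd window (default 3×3) with reflect padding, and the unit
tests pin it to a naive double-loop oracle at 10⁻¹² — border behavior
included.

**MSMG fusion.** The multi-scale morphological gradient is
`M = Σₜ wₜ Gₜ`, `Gₜ = f ⊕ SEₜ − f ⊖ SEₜ`, `wₜ = 1/(2t+1)` (so 1/3, 1/5, 1/7
at the default N = 3). The printed SE recursion is self-referential; we read
it as the standard construction `SEₜ = SE₁` dilated t−1 times. The base
element is the 5-pixel discrete disk of radius 1 (the city-block cross), so
`SEₜ` is the L1 ball of radius t. Dilation and erosion take the extremum
over in-bounds neighbors only, which keeps `M ≥ 0` everywhere including
borders. No canonical combination rule exists for fusing the two
copies; we use MSMG as a focus measure, with a soft blend
`ρ = logistic(4·(M_A − M_B))` by default and a hard per-pixel argmax
(ties to the first input) as an option. Which pair is fused — enhanced +
filtered (default) or enhanced + original — is a config switch; the former is the
default. The focus
measure discriminates sharp from blurred content only where the scene has
fine-grained detail; on smooth low-frequency regions the two MSMG maps tie
and the blend defaults to the first input.

## The layer library

No tensor/autograd framework is available to R here, so the package carries
a small reverse-mode layer library of its own: conv2d via im2col plus one
BLAS GEMM (the im2col/col2im and depthwise loops are compiled C++ under
`src/`), depthwise convolution, batch normalization (momentum 0.1,
ε = 10⁻⁵), squeeze-excite/channel attention, nearest and bilinear ×2
upsampling (half-pixel centers), global average pooling, dropout, dense
layers, softmax cross-entropy, and Adam/SGD updates over nested parameter
trees. Every primitive's backward pass, and the composed PCFAN and
classifier losses, are checked against central finite differences in the
test suite; that is the correctness anchor for everything trained below.
Tensors are dense doubles in (H, W, C, N) layout.

## PCFAN

The encoder has three stages — a 3×3 convolution to 32 channels plus two
residual blocks (conv–ReLU–conv with identity skip, the standard form), then two stride-2
stages doubling the width to 64 and 128 while halving resolution. Inputs are
zero-padded to multiples of 4 so the pyramid shapes are exact. The channel
attention block squeezes a feature map to its per-channel global-average
descriptor, reduces by r = 8, applies ReLU, expands back and gates through a
sigmoid; the attended map is the elementwise product, so attention can only
attenuate, never amplify. The pyramid fusion (PCFA) instantiates exactly
four attention blocks, two upsamplings and two concatenations in a fixed
top-down wiring: CA(f₃) upsampled and concatenated with CA(f₂); that
concatenation attended again, upsampled, concatenated with CA(f₁), and
mapped by a 1×1 convolution back to the stage-1 width. Descriptions of this
fusion in the literature fix the block counts but not the wiring; this one is
our fixed choice. Reconstruction is a single 3×3 convolution plus
sigmoid.

PCFAN is pretrained self-supervised — the target is the input image itself
(optionally noise-corrupted inputs with clean targets) — because no "clean"
reference exists for MR slices; the MSE loss is the only loss (an
additionally named edge-aware loss has no printed formula anywhere and is
out of scope). Per-epoch losses are evaluation-count-weighted means over
batches, so they are invariant to shuffling order, and a zero learning rate
provably leaves the loss history flat. PCFAN and the classifier are trained
sequentially; the reconstructed single-channel image (not the 32-channel
map) is what a PCFAN-enabled pipeline feeds to the classifier, keeping the
classifier input single-channel.

In the end-to-end desk configuration the PCFAN stage is *disabled by
default*: pretraining the full-width network on 128×128 slices is a
GPU-scale workload, far outside a single-CPU run. The module is fully
implemented and tested (at reduced width 8/16/32 and 32×32 phantoms, which
exercises identical code paths), and one config flag turns the stage on.

## The classifier

A reduced 6-block MobileNetV3-style schedule (stem 3×3 stride-2 convolution
with batch norm and h-swish; bneck blocks `(in, expand, out, k, stride, SE,
act)` = (16,16,16,3,2,SE,relu), (16,72,24,3,2,–,relu), (24,88,24,3,1,–,relu),
(24,96,40,5,2,SE,hswish), (40,240,40,5,1,SE,hswish), (40,120,48,5,1,SE,
hswish); head 1×1 convolution to 96, global average pool, dropout 0.2,
linear softmax head). All widths scale by the width multiplier (default
0.5), rounded to multiples of 8 with a floor of 8; squeeze-excitation uses a
hard-sigmoid gate and reduction 4 on the expanded width; h-swish is
`x·ReLU6(x+3)/6` exactly. The full MobileNetV3-Small schedule is
reconstructible through `modelConfig()`, but the reduced schedule is the
default because the method prescribes the architecture family, not a size,
and single-CPU training governs the default.

Training is cross-entropy with Adam at learning rate 0.001 and batch size
32, the method's stated training regime; its 200 epochs are replaced by a
30-epoch desk default, with the long regime one config value away. Momentum
(0.9) is listed alongside Adam in that regime without being reconciled;
here it applies when SGD is selected and is ignored by Adam. Training metrics
accumulate over the training-mode minibatch outputs; validation metrics use
an evaluation-mode pass (running batch-norm statistics) at each epoch end.
With a zero learning rate neither parameters nor batch-norm state are
updated, so nothing about the model changes.

## IDMO

The optimizer minimizes over a box, with the population as an n×d matrix
initialized uniformly, `X = rand·(U−L)+L`. Each iteration runs three phases:

- **alpha**: every non-babysitter proposes
  `α + ω·φ·r·(Xₐ − Xᵤ)`, greedy-accepted (kept only on improvement), with
  `ω = e^{−4(C/Max)²}`;
- **scout**: `α + φ·r·(Xᵤ − Xᵥ)/2`, same acceptance;
- **babysitter**: on a countdown (reset value 6) the worst-fitness third of
  the population — never the current alpha — is replaced by
  `X_b + r·(α − (Xᵤ+Xᵥ)/2)·br·CF`, `CF = (1−C/Max)^{2C/Max}`, with the
  birthrate br drawn uniformly per update unless fixed.

Four quantities the printed equations leave open are resolved as follows,
and all are config fields. (1) φ is drawn from U[−1, 1]. (2) φ and r are
drawn *per dimension*: with scalar draws every candidate lies on a line
through α, the population collapses onto low-dimensional affine subspaces
and convergence stalls by one to two orders of magnitude on the sphere
benchmark; independent per-dimension draws restore full-rank exploration.
(3) Peers u, v are drawn from the *whole* population, not only the foragers
— reserve babysitters are refreshed only every few iterations, so they
preserve diversity and keep difference-vector step sizes from collapsing
prematurely. (4) ω is part of the method's definition yet appears in none of its
printed updates; it is applied as the alpha-phase step damper (and CF in the
babysitter phase), and `useOmega = FALSE` runs the undamped literal reading.
Bounds are enforced by clipping (resampling available); minimization is the
convention, maximize by negating. The trace logs best/mean fitness and the
exact evaluation count per iteration; the total is bounded by
n·(2·maxIter + 1).

For hyperparameter tuning the search space is: log₁₀ learning rate in
[−4, −1]; batch size from {8, 16, 32} through a rounded index; log₁₀ weight
decay in [−6, −2]; dropout in [0, 0.5]; width multiplier in [0.25, 1]. The
objective is the validation error of a short proxy training run (reduced
epochs, fixed seed per evaluation) rather than a full run per candidate —
the tuning protocol of the original study is unreported, and proxy
objectives are the standard desk-scale substitute. Dimensions with
`low == high` are held fixed; a fully collapsed space is evaluated once per
individual and returned.

## Metrics

One-vs-rest confusion counts per class; accuracy (TP+TN)/total, sensitivity
TP/(TP+FN), specificity TN/(TN+FP), precision TP/(TP+FP), F-measure as the
harmonic mean. A frequently mis-printed formula gives sensitivity as
TP/(TP+FP), contradicting the standard definition of recall; the recall
form is the default and the printed form remains selectable
(`sensitivityFormula = "printed"`). Zero denominators yield a sentinel 0
and the metric name is recorded in an `"undefined"` attribute rather than
silently propagating NaN. The multi-class rollup is macro (unweighted) by
default with a support-weighted option: macro is threshold-free and
class-balanced, and reported single-number summaries of this method do not
state their aggregation. ROC curves sweep the
unique score thresholds (ties cross simultaneously) and AUC is the
trapezoid integral, which equals the Mann–Whitney pairwise statistic with
half-credit ties.

## Reproducibility and problem sizes

Every stage derives its own seed from the master seed, and seeded helpers
save and restore the caller's RNG state. The canonical pipeline report
(metrics, per-stage seeds, configuration, final-epoch summary) contains only
deterministic quantities — wall-clock timings are returned and written
separately — so a same-seed rerun reproduces `report.json` bit-for-bit.

Default problem sizes, chosen as single-CPU desk scale: 300 phantoms
(100/class) at 128×128 with the width-0.5 classifier and 30 epochs for the
end-to-end run; 64 phantoms at 32×32 with the 8/16/32-width PCFAN for
pretraining demonstrations; sphere d=5 (n=30, 100 iterations) and Rastrigin
d=2 (200 iterations, 20 seeds, compared to random search at the identical
evaluation budget) for the optimizer; finite-difference gradient checks on
tensors of a few hundred elements.

## Known limitations

- The phantom task is far easier than clinical severity grading; the 0.90
  end-to-end bar certifies machinery, not medicine.
- The printed positive BTF exponent makes the default enhancement nearly an
  identity on dark-background slices (see above); users wanting true
  low-light brightening should set the negative-exponent constants.
- Batch norm couples predictions within a training batch; exact histories
  are reproducible only under fixed seeds and single-threaded BLAS.
- The layer library is CPU-bound R/C++ at double precision: fine at desk
  scale, not a platform for 200-epoch full-resolution studies.
- IDMO's open constants (φ range, babysitter timer, birthrate) follow the
  documented defaults; other readings of the printed equations are runnable
  through the config but were not tuned.
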