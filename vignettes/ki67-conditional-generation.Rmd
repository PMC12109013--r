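---
title: "Ki67-conditioned generation and evaluation of HE histology patches"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ki67-conditioned generation and evaluation of HE histology patches}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

The Ki67 index — the fraction of a tissue patch occupied by
immunohistochemically positive (DAB-brown) staining — quantifies cell
proliferation and is a mandatory step in many tumour diagnostic work-ups.
Ki67 staining is, however, expensive and slow compared with routine
Hematoxylin and Eosin (HE) staining.  A conditional generative model that
produces HE patches *conditioned on a Ki67 index* lets one ask the converse
question: what does proliferation look like in HE alone?  Sweeping the
condition for a fixed latent vector produces counterfactual sequences, a
building block for explainable Ki67-from-HE prediction.

`ki67gan` implements that programme end to end at desk scale: a simulator
of paired HE/Ki67 patches with known ground truth, the semi-automated Ki67
annotation pipeline, a compact Ki67-conditioned style-mapping GAN trainable
on one CPU, the Fréchet/perceptual metric suite used to evaluate such
generators, the Ki67-interval evaluation protocol, sweep-sequence
generation, and the ordinal analysis of expert realism verdicts.

## The synthetic patch-pair simulator

Real datasets of this kind pair each HE patch with an adjacent-section Ki67
patch cut from the same position, so both share one tissue layout.  The
simulator (`render_patch_pair()`) emulates exactly the features downstream
stages consume and nothing more:

* **Shared nuclei layout.** Nuclei are random ellipses (about 30 px² at the
  default 64×64 patch size), placed with limited overlap.  The HE rendering
  shows all nuclei hematoxylin-purple on an eosin-pink background; the Ki67
  rendering recolours a subset DAB-brown and the rest hematoxylin-blue on a
  pale IHC background.
* **Ground truth by construction.** The target index `p` is the brown-pixel
  fraction over *all* pixels of the patch — the same definition the
  annotation pipeline quantifies — and the realised `true_index` is counted
  from the rendered positive mask, so annotation-recovery tests close the
  loop exactly.  Nucleus-level granularity makes the realised fraction track
  the request to within ~0.01–0.03.
* **Coverage calibration.** Nuclei coverage is `p + 0.12` (capped at 0.88).
  Coverage must exceed `p` for the brown subset to exist, and tying it
  linearly to `p` mirrors the biological expectation that proliferative
  tumour carries more, denser cells.  It is also what makes the index
  visible in HE alone; `estimate_he_index()` inverts the calibration from
  the dark-pixel (hematoxylin) fraction.  Requests above the achievable
  coverage are clamped with a warning.
* **Label imbalance.** `label_distribution("paper-imbalanced")` emulates the
  heavily skewed label distributions of real seminoma patch collections:
  a Beta(1, 12) body with a small Uniform(0.4, 1) tail, mixed 0.976/0.024 so
  that P(index > 0.5) = 0.020 — matching the reported ~2% share above 0.5
  with the mode below 0.1.  Only the interval shares of the real
  distribution are published; the parametric form is this package's
  stand-in, chosen once.
* **Defects for filter testing.** `degrade()` produces out-of-focus patches
  (Gaussian blur, default σ = 5 px), blank glass (near-uniform white),
  tearing artifacts (a white band covering 75% of the patch by default) and
  sparse-tissue patches (4 remaining nuclei).

What the simulator does **not** emulate: tissue architecture (glands,
stroma, necrosis), stain physics, scanner noise, or cell-level
morphological correlates of proliferation.  Passing tests therefore show
that the *pipeline arithmetic* is correct and that conditioning information
flows end to end; they say nothing about realism on actual tissue.

## The annotation pipeline

`compute_ki67_index()` follows the semi-automated labelling recipe:
k-means clustering of the Ki67 patch in CIE Lab space (k = 3 by default:
positive brown / negative blue / background) and the index as the fraction
of pixels in the brown cluster.  The brown rule on a cluster centroid is
HSV hue ∈ [15°, 50°], saturation > 0.2, value ∈ [0.15, 0.85] — isolating
DAB brown from hematoxylin blue and white glass.  Ties between brown
centroids go to the larger cluster; with no brown centroid the index is
exactly 0.

Two open choices are exposed as parameters rather than hard-coded:

* **Denominator.** The literal index definition divides by all patch
  pixels; `denominator = "tissue"` excludes near-white background cluster
  pixels instead.  The all-pixels reading is the default and is what the
  simulator's ground truth uses.
* **Filter thresholds.** The published pipeline defers filter details to
  prior work, so `quality_filter()` is config-first with logged defaults:
  Laplacian variance ≥ 50 (8-bit scale, blur detection), Sobel edge density
  ≥ 0.02, dark connected-component count ≥ 10 (blob detection), tissue
  fraction ≥ 0.3, and an intensity-sd blank rule (< 10).  These defaults are
  not claimed to match the original pipeline's values; they are calibrated
  to the simulator's rendering so that clean patches pass and each
  degradation mode fails for its own reason.

## The conditional GAN

The conditioning contract is the conditional mapping network: the scalar
Ki67 index is embedded by one fully connected layer to the width of the
intermediate latent space W, normalised exactly like the input latent
(`x / sqrt(mean(x²) + 1e-8)`), concatenated with the normalised `z` and
passed through two fully connected layers to produce `w`.  The embedding
input is the raw scalar index — the condition is continuous, not a class.

Around that contract sits a compact CPU-trainable architecture in place of
alias-free full-scale synthesis (explicitly out of scope here):

* **Synthesis.** A learned 4×4 constant followed by four
  upsample–modulate–convolve–leaky-ReLU blocks to 64×64; `w` enters every
  block through a learned affine producing per-channel feature scales
  (initialised to 1).  A 1×1 convolution maps to RGB; output is linear
  during training and clamped to [0, 255] at generation.
* **Discriminator.** A two-hidden-layer leaky-ReLU MLP on 2×-downsampled
  patches with projection conditioning,
  `D(x, c) = f(x) + c · v,h(x)`.  Whether the original conditions its
  discriminator by projection or concatenation is not described; projection
  is the choice here.
* **Losses.** Non-saturating logistic loss plus the R1 penalty
  `γ/2 · E‖∇ₓD‖²` on real batches with γ = 2 by default.  Because the
  discriminator is piecewise linear, the penalty's parameter gradient has a
  closed form (activation patterns held fixed), which is exact almost
  everywhere; `γ = 0` removes the term identically.  Both facts are
  unit-tested against finite differences.
* **Optimisation.** Adam (β₁ = 0, β₂ = 0.99), learning rate 2·10⁻³,
  batch 32.  Progress is counted in kimgs (thousands of real images shown).
  Adaptive discriminator augmentation is replaced by fixed random
  flips/transpositions applied in the discriminator step, recording the
  substitution.
* **Fakes are conditioned on labels resampled from the training label
  distribution**, so the generator is asked for the same imbalanced mix it
  must imitate.

Desk defaults — `z_dim = w_dim = 64`, 64×64 output, channels
32→24→16→12→8, 50 kimgs on 2,000 simulated pairs — train in roughly ten
minutes on one CPU core.  FID and PPL are logged every 10 kimgs the way
training-progress curves for such models are usually read; the known
qualitative effect that PPL can *rise* late in training (entangling latent
space as the model overfits) is reported in the log but never asserted as a
test, since it is an empirical observation, not a guarantee.

Training is deterministic given the config seed: two runs produce
identical logs and weights.

## Metrics

* `frechet()` implements the squared Fréchet distance between Gaussians in
  the FID convention, `‖Δμ‖² + tr(Σₐ + Σᵦ − 2(ΣₐΣᵦ)^{1/2})`, with the
  matrix square root via an eigendecomposition of the covariance product, a
  10⁻¹⁰ jitter fallback, and clipping at zero.  Covariances use the n−1
  divisor.  Tests cross-check against the independent
  `Σₐ^{1/2}ΣᵦΣₐ^{1/2}` diagonalisation oracle.
* `fid()` embeds both image sets with a *visual* embedder.  At desk scale
  the default is a fixed-seed random-feature CNN (untrained backbone +
  random projection): random convolutional features preserve the colour and
  coarse texture statistics these comparisons need, and the embedder
  contract (`new_embedder()`) accepts any pretrained substitute.
* `fhd()` is FID with the embedder replaced by the *histological* embedder:
  `train_histological_embedder()` fits a small CNN regressor predicting the
  Ki67 index from the HE patch and embeds images as its penultimate
  fully-connected activations.  Which internal layer supplies features is
  not specified in the source method; the penultimate layer is the default
  here.
* `ppl()` measures latent-space entanglement: the mean of
  `d(G(t), G(t+ε))²/ε²` over random pairs, with spherical interpolation in
  input-latent space (or linear in W), ε = 10⁻⁴, and the perceptual
  embedder supplying `d`.  The conditioning label is drawn once per pair
  from the training label distribution and held fixed along the path —
  per-interval PPL does not define label handling along the path, so this
  is the package's choice.

## The interval protocol

`ki67_intervals()` builds the six evaluation intervals
⟨0.5,1⟩, ⟨0,0.5), ⟨0.2,0.5), ⟨0,0.2), ⟨0.1,0.2), ⟨0,0.1); all relations
(identical / subset / complementary) are derived from bounds, never
asserted.  `metric_matrix()` computes full FID/FHD cross matrices between
interval image sets, flags each cell with its expectation (diagonal /
expect-low for subsets / expect-high for complementary pairs), reports
undersized sets as missing rather than zero, and keeps full precision
internally (rounding only at rendering).

`check_relations()` mirrors the emphasised-anomaly reading of such tables:
a violation is a complementary (expect-high) cell that falls below its
row's or its column's diagonal.  The diagonal is deliberately *not*
required to be the global row minimum, and complementary cells are not
compared against subset cells: in published matrices subset cells sit
marginally below the diagonal in several rows as a consequence of label
imbalance and are read as expected there, so stricter rules flag behaviour
the protocol treats as normal.  On the transcribed reference tables the
detector reproduces exactly the anomalies the protocol's narrative flags.

## Sequences and ratings

`generate_sequence()` implements the sweep protocol: six images per
sequence, one latent vector per sequence, Ki67 from 0 to 0.5 in steps of
0.1.  Grids above 0.5 warn — generators trained on imbalanced data are
least reliable there.  Since no quantitative image-level realism criterion
exists for sweeps, the package's trend statistic is an artifact-level
proxy, not a reimplementation of expert review: the Spearman rank
correlation between the grid and the annotation module's HE index proxy,
with constant (all-tied) recoveries defined as 0 plus a warning.

`read_ratings()` ships the transcription of the two published expert
evaluation groups (20 sequences × 2 pathologists each, 5-level verdicts).
The ordinal distance is the absolute difference of the encoded levels
(0–4); that metric reproduces every published consistency figure — 70%
consistency with maximum distance 2 for the first group, 55% with maximum
distance 4 for the second — together with all histogram and category
splits, which is the transcription's integrity check.

## Numerical choices and degenerate inputs

* Guarded second-moment normalisation uses ε = 10⁻⁸; an all-zero latent is
  well-defined.
* k-means is seeded (`nstart = 3`); when an image has fewer distinct
  colours than k, clustering falls back to the distinct colours with a
  warning; degenerate centre draws re-seed from colours spread along the
  lightness axis.
* Fréchet eigenvalues are clipped at 0 before the square root; non-finite
  results abort rather than propagate.
* Training aborts with a diagnostic on non-finite losses;
  `total_kimgs = 0` returns the initial checkpoint and an empty log.
* Empty manifests produce empty labelled manifests; unreadable rows are
  marked failed and skipped, never dropped silently.

## Problem sizes

The package's own test and reference runs use: 10⁵ draws for label-law
checks, 1,000 pairs for annotation recovery, 400 patches for filter
precision/recall, 2,000 pairs / 50 kimgs / 64×64 for the end-to-end
conditioning-recovery run, 50 images per condition for the conditioning
sweep, and 20 sequences per group — small enough to run on a laptop core,
large enough that the stochastic checks are stable under their fixed
seeds.

## Known limitations

* Random-feature embedders are colour/texture statistics, not semantic
  features; FID values are not comparable to Inception-based numbers, and
  paper-scale metric values (which require the study dataset and GPU-scale
  training) are out of reach by design.
* The HE index proxy depends on the simulator's coverage calibration; on
  real tissue the dark-pixel fraction is a crude nuclear-density surrogate
  and only its monotone use (rank statistics) is defended here.
* The GAN is compact: it learns colour/coverage statistics of the
  simulator, not histological morphology.
* Ellipse packing caps achievable indices near 0.88; requests above are
  clamped (with the warning logged).
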