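# ki67gan

Ki67-conditioned generation and evaluation of synthetic HE histology
patches, in R.

The Ki67 index of a tissue patch — the proportion of immunohistochemically
positive (DAB-brown) pixels in its Ki67-stained section — quantifies cell
proliferation. Routine diagnosis starts from cheap Hematoxylin & Eosin (HE)
staining; Ki67 IHC is slow and expensive. A generative model that produces
HE patches *conditioned on a Ki67 index* lets one study how proliferation
is expressed in HE appearance alone, and produces counterfactual image
sequences (same tissue layout, rising Ki67) that support explainable
Ki67-from-HE prediction. This package is for researchers in computational
pathology and generative-model evaluation who want that whole pipeline —
data, model, metrics, and evaluation protocols — runnable and testable on a
single CPU.

## What is inside

* **`synthdata`** — a simulator of adjacent-section HE/Ki67 patch pairs
  with known ground-truth indices (one shared nuclei layout per pair, a
  brown-recoloured subset in the IHC rendering), the heavily imbalanced
  label law of real seminoma patch collections (P(index > 0.5) = 0.02,
  mode < 0.1), and controllable defects (blur, blank, tear, sparse) for
  filter testing.
* **`annotate`** — the semi-automated annotation pipeline: k-means colour
  clustering of the Ki67 patch in Lab space, the index as the brown-cluster
  pixel fraction, and a quality filter (Laplacian-variance blur detection,
  edge density, blob count, tissue fraction).
* **`cgan`** — a compact Ki67-conditioned style-mapping GAN. The scalar
  condition is embedded to the width of the intermediate latent space W,
  normalised like `z` (`x / sqrt(mean(x^2) + 1e-8)`), concatenated and
  passed through two FC layers to give `w`, which modulates every block of
  a 4-block convolutional synthesis stack. Training uses the
  non-saturating logistic loss with an R1 penalty
  `gamma/2 * E||grad_x D||^2` (default `gamma = 2`), counts progress in
  kimgs, and logs FID/PPL. Backpropagation (including the closed-form R1
  parameter gradient) is implemented in the package with RcppArmadillo
  convolution kernels.
* **`metrics`** — the squared Fréchet distance in the FID convention
  `||Δμ||² + tr(Σ_a + Σ_b − 2(Σ_a Σ_b)^{1/2})`, FID, FHD (the embedder
  replaced by a CNN trained to predict Ki67 from HE; features from its
  penultimate layer), and perceptual path length, all against a pluggable
  embedder contract.
* **`intervals`** — the Ki67-interval evaluation protocol: the hierarchy
  ⟨0.5,1⟩, ⟨0,0.5), ⟨0.2,0.5), ⟨0,0.2), ⟨0.1,0.2), ⟨0,0.1); FID/FHD cross
  matrices with subset/complement expectation flags; a violation detector
  for "unexpected" cells; the published reference matrices as fixtures.
* **`sequences`** — Ki67 sweep sequences (six images, one latent vector,
  Ki67 = 0 → 0.5 in steps of 0.1) and a rank-correlation trend statistic.
* **`ratings`** — the two pathologists' 5-level verdicts of the two
  published sequence groups as a transcribed fixture, with ordinal
  inter-rater distances, consistency fractions and category summaries.

## Worked example

```r
library(ki67gan)

# one synthetic pair and its annotation
pair <- render_patch_pair(0.3, size = 64, seed = 1)
pair
#> <patch_pair> patch  64x64  true_index = 0.3010
compute_ki67_index(pair$ki67_image)
#> [1] 0.3010254
quality_filter(pair$he_image)
#> <filter_decision> keep = TRUE

# a simulated dataset through the annotation pipeline
ds  <- render_dataset(200, seed = 42)
lab <- label_dataset(ds)
#> label_dataset: kept 192 / 200 patches
#>   excluded by reason: low-blob-count=8
mean(abs(lab$ki67_index[lab$keep] - lab$true_index[lab$keep]))
#> [1] 0.000645  # the clustered index recovers ground truth almost exactly

# ordinal analysis of the expert verdicts
r <- read_ratings()
rating_consistency(r, group = 1)
#> <ki67_consistency> 20 sequences: 70% consistent (distance <= 1), max distance 2
rating_categories(r, group = 1)
#> # A tibble: 9 x 4
#>   rater    category  count fraction
#> 1 1        unreal        3     0.15
#> 2 1        partially     8     0.40
#> 3 1        real          9     0.45
#> ...
#> 9 combined real         18     0.45
```

The `true_index = 0.3010` / recovered `0.301` pair shows the closed loop:
the simulator's ground truth is defined exactly as the annotation pipeline
measures it. The consistency line and category fractions are the package's
recomputation of the published expert-evaluation statistics from the
transcribed verdict tables.

Training and sweeping the conditional generator:

```r
fit <- train_cgan(lab, cgan_config(total_kimgs = 50, gamma = 2, seed = 1))
tidy(fit)                     # kimgs, fid, ppl, losses
g <- generate_conditional(fit$checkpoint, c = 0.4, n = 50, seed = 2)
grp <- generate_sequence_group(fit$checkpoint, n = 20, seed = 5)
tidy(grp)                     # per-image recovered index and trend
```

On the desk defaults (2,000 pairs, 64×64, 50 kimgs, one CPU core,
~10 minutes) the Spearman correlation between the conditioning value and
the annotation module's recovered index of generated images is about 0.66
over c ∈ {0, 0.1, …, 0.5} × 50 images, and all 20 sweep sequences show a
positive trend while a label-shuffled control centres on zero.

A thin command-line wrapper over the same functions is installed at
`inst/cli/ki67gan.R` (`Rscript ki67gan.R synthdata make --n 200 --seed 1
--out data/`, `... cgan train`, `... sequences make`, `... ratings
analyze`, and so on).

## Vignette

`vignettes/ki67-conditional-generation.Rmd` documents the model and its
assumptions, the simulator's calibration and its limits, every tunable
parameter with units and defaults, the numerical choices, and what desk
scale does and does not demonstrate.
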