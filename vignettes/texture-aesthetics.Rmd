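---
title: "Methods: white-box modeling of aesthetic texture perception"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: white-box modeling of aesthetic texture perception}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aestex)
library(dplyr)
```

## The problem and the model

People attach aesthetic feelings to visual textures — a texture looks warm or
cold, elegant or inelegant, and ultimately liked or disliked. `aestex`
implements an interpretable ("white-box") pipeline that predicts such
semantic-differential ratings from computable image statistics, organised as
a three-layer feed-forward hierarchy inspired by staged accounts of
aesthetic processing:

* **Affective layer** `G = F1(M) + R0` — three first-glance properties
  (cold–warm, rough–smooth, dark–light) predicted from low-level features
  `M`.
* **Judgment layer** `T = F2(M) + F3(G) + R1` — four properties describing
  the nature of the texture (mussy–harmonious, inelegant–elegant,
  simple–complex, artificial–natural) predicted from features *and* the
  affective outputs.
* **Emotional layer** `Q = F4(M) + F5(G) + F6(T) + R2` — the like–dislike
  decision, fed by everything upstream.

The activations `F1..F6` are sums of explicit symbolic terms, so every fitted
model can be read, differentiated and criticised term by term. The thresholds
`R0, R1, R2` are the minimum observed training rating of each layer — an
"emotion threshold" offset — and the expressions are fitted to
threshold-subtracted ratings. Information flows only forward: perturbing
judgment values can never change affective outputs, which the test suite
asserts mechanically by symbolic dependence extraction.

Ratings live on a continuous open scale `(-100, 100)`, collected from a
panel (20 raters by default) and aggregated per texture and property after
outlier screening.

## The 106-feature catalog

Each texture yields exactly 106 features in a fixed order
(`feature_catalog()`), grouped as 3 + 64 + 3 + 36:

* **Color (3)** — means of hue, saturation and value after RGB→HSV
  conversion, all on `[0, 1]`. Achromatic pixels have hue 0. Conversion uses
  the standard `grDevices` HSV definition.
* **Co-occurrence (64)** — contrast, correlation, energy and homogeneity of
  gray-level co-occurrence matrices at distances `d ∈ {2, 4, 6, 8}` and
  orientations `θ ∈ {0°, 45°, 90°, 135°}`. Luminance (BT.601 weights) is
  quantized to `L = 16` levels by uniform binning of `[0, 255]`; counting is
  symmetric (each pair counted in both directions) and normalized to
  probabilities, which makes 180°-complement orientations redundant and
  yields exactly 4 × 4 × 4 = 64 values. The published selected-feature table
  names only contrast and homogeneity among these; the four-statistic set is
  this package's documented completion of the "4 statistics × 4 × 4" count,
  using the most common Haralick subset. Distance 2 is likewise an
  assumption: the published table shows d = 4, 6, 8 and four levels are
  required.
* **Tamura (3)** — coarseness (mean optimal dyadic window size `2^k`,
  `k = 1..5`, ties to the smallest window so a flat image scores 2),
  contrast (`σ / α₄^{1/4}` with kurtosis `α₄ = μ₄/σ⁴`, population moments,
  0 for flat images), and directionality (one minus the normalized second
  moment of a 16-bin gradient-orientation histogram about its peak; Prewitt
  masks, magnitude threshold 12 on the 0–255 scale; 0 with a warning when no
  gradient clears the threshold).
* **Wavelet (36)** — per-coefficient L1 norm, L2 norm and Shannon entropy of
  the horizontal, vertical and diagonal detail subbands of a 4-level 2-D
  Daubechies-4 (4-tap D4) decomposition: 3 × 3 × 4 = 36. Norms are averaged
  per coefficient; entropy uses `p_i = c_i²/Σc²` with natural logarithm and
  `0·log 0 = 0`.

### Numerical choices

* **Wavelet boundary handling is periodization.** The energy-signature
  features are built on energy bookkeeping, and only a strictly orthonormal
  transform satisfies the Parseval identity `Σ(details²) + Σ(approx²) =
  Σ(image²)` that the test suite checks to 1e-6 relative (measured error is
  at machine precision). Symmetric extension with orthogonal filters
  violates this at boundaries, so it is not used. Odd dimensions are
  edge-padded per level; exact conservation is guaranteed for sides
  divisible by 16.
* **Numerical dust suppression.** Detail coefficients with magnitude below
  1e-9 (on the 0–255 intensity scale) are treated as exact zeros before
  subband statistics, so flat images produce exactly zero signatures instead
  of entropies computed from rounding noise.
* **Degenerate conventions** are explicit everywhere: co-occurrence
  correlation is 0 when a marginal variance vanishes; Tamura contrast is 0
  for flat images; coarseness tie-breaks to the smallest window.

## Feature selection

`nca_fit()` implements neighborhood component analysis for regression with a
diagonal metric: sample `i` selects neighbour `j` with probability
`p_ij ∝ exp(-Σ_m w_m² |x_im - x_jm|)` (`p_ii = 0`), and the weights minimize
the expected leave-one-out absolute error `Σ_ij p_ij |y_i - y_j| / n` plus an
L2 penalty `λ Σ w_m²` (default `λ = 1/n`). Squaring the weights inside the
distance keeps the effective weights non-negative without constraints.
Optimization is deterministic gradient descent from all-ones with a
backtracking step, so the objective trace is non-increasing and results are
bit-reproducible; standardization of the columns (on by default) is
essential because the distance is scale-sensitive.

The model pipeline defaults to the frozen published selection
(`reference_catalog()`): ten features `f1..f10` — mean saturation, five
co-occurrence statistics, Tamura coarseness and directionality, and the two
level-1 wavelet norms — with their published weights. Re-running NCA needs
rating data that cannot be shipped, so re-selection is an explicit step
(`nca_fit()` + `rank_and_select()`, or the `select` CLI command). The source
text is inconsistent about whether 8 or 10 selected features feed the model;
this package follows the ten-feature reading, which is the one the reference
equations actually use. Which response variable drove the published ranking
is also unstated, so the selection interface takes an explicit `--property`
choice rather than claiming either.

## Rating aggregation

The outlier rule is unspecified in the source; the package uses a single-pass
mean ± 2 SD screen per (texture, property) panel, retaining everything when
the SD is 0 and never removing more than 25% of a panel (the most extreme
quarter is dropped when more is flagged). A clean Gaussian panel of 20
occasionally loses a score under any 2-SD rule (~4.6% of scores); the
relevant property, which the tests assert, is that the expected retained
fraction stays near 1 while genuinely extreme injected scores are removed at
a high rate (≥ 80% required; ~93–94% measured under the default study).

## The frozen reference model

`reference_model()` ships the published fitted equations as expression trees
and evaluates them in exact double precision — no hidden normalization. Two
transcription ambiguities are handled explicitly:

* One judgment-layer term is typeset as a run-on product missing its
  fraction bar; it is implemented as `-(f8·G3)/(f1·f3·G1)` (the plausible
  fraction reading), with the plain-product alternative available via
  `reference_model(eq7 = "product")` for sensitivity analysis. A zero
  denominator raises a domain error naming the term.
* Whether the printed coefficients apply to raw or preprocessed features is
  unstated. Both paths exist: `predict_layers()` evaluates raw features by
  default and accepts a `transform` record, because no canonical training
  statistics exist without the original image set, and silently applying an
  arbitrary transform would misrepresent the published coefficients.

Model complexity is reported as the binary-tree node count of an expression
(each constant, variable occurrence and operator counts 1; a unit
coefficient on a non-constant term adds nothing). Under this rule the
two-term linear equation of the rough–smooth property counts 5, matching its
published complexity. The published complexity metric is nominally a
VC-dimension, but no computation is given; node count is the computable,
size-monotone convention used by symbolic-regression tools.

## Refitting the hierarchy

`fit_hierarchy()` is a deterministic, desk-scale replacement for the
proprietary evolutionary search used to obtain the published equations — a
method substitution, not a reproduction:

1. **Preprocessing** (`preprocess_features()`): per feature, winsorize at
   median ± 3 MAD ("data smoothing"), then z-score with the mean and
   population SD of the winsorized training values. Statistics come from
   training rows only and the transform record replays exactly on new rows.
2. **Split** (`split_train_test()`): seeded random 90/10 partition
   (`round(0.9 n)` training rows). Whether the original split was stratified
   is unknown; seeded-random is the documented default.
3. **Basis** (`build_basis()`): constant, linear, square and pairwise
   product terms (degree 2, the degree of the published equations), plus
   optional unary `sin/cos/tan/exp/log/sqrt` transforms and optional
   pairwise quotients (off by default — the one published ratio term is
   domain-fragile). Terms that are non-finite on any training row are
   dropped. The factorial, though nominally in the published operator
   library, is excluded: it appears in no printed equation and is
   ill-defined on reals.
4. **Greedy selection** (`fit_layer()`): starting from the constant, add the
   candidate that most reduces `MAE + α·complexity`, least-squares refit of
   all coefficients each step, skip singular additions, stop at `max_terms`
   (default 7) or no improvement. `α = 0.01` rating units per node by
   default — small enough that any real term earns its place, large enough
   that a noiseless linear target stops at the exact two-term answer (a
   property the suite asserts). With a huge `α`, every fit collapses to the
   constant model.
5. **Stages**: affective fits see 10 inputs; judgment fits see 13 (features
   + *fitted* affective values, never observed ones); the emotional fit sees
   17. Held-out rows influence nothing upstream — scrambling their values
   leaves the fitted model bit-identical, which the suite verifies.

## What the generators emulate — and what they do not

`gen_texture_suite()` spans gratings, checkerboards, filtered noise and blob
fields over seeded Latin-hypercube ranges of orientation (0–180°), scale,
contrast (0.3–1), hue and saturation, at 64 × 64 pixels by default; every
one of the 106 features has nonzero variance across a 50-texture suite.
`gen_annotation_study()` scores each texture with a rater panel: truth plus
Gaussian noise (SD 5), a 5% chance of an extreme replacement (deviation
45–85 units, logged for efficacy measurement), clamped strictly inside
`(-100, 100)`.

The planted ground truth (`plant_hierarchy()`) is deliberately a simplified,
basis-realizable hierarchy — per property an intercept, two linear terms and
one product over robust-standardized features, plus one upstream term for
the higher layers — rather than the full reference equations, whose ratio
term is undefined on arbitrary synthetic features (the reference model
remains available as an alternative truth). Feature standardization inside
the generator clips at ±3 robust SDs, modelling saturation of the perceptual
response to extreme feature values; true ratings are clamped to ±90 so rater
noise rarely hits the scale boundary.

Passing the recovery suite therefore demonstrates that the pipeline recovers
*planted, realizable* structure through real feature extraction, screening,
and staged fitting — it does not demonstrate that human aesthetic ratings of
photographic textures are predictable at any particular accuracy. Procedural
patterns are far more regular than material photographs, raters here are
exchangeable Gaussian noise sources without cultural or demographic
structure, and the published headline accuracies depend on a request-only
image set and human panel that cannot be redistributed.

## Problem sizes and reproducibility

The validation suite runs at deliberate desk scale: 100-texture suites at
64 × 64 with 20 raters over 10 seeds for hierarchy recovery (median held-out
affective correlation ≈ 0.99 against the ≥ 0.9 requirement), 20 seeded runs
at n = 200, p = 5 for selection recovery, 20 random images for each kernel
oracle (co-occurrence agreement at 1e-10, energy conservation at machine
precision), and a 256 × 256 image for the single-image extraction benchmark
(≈ 0.1 s). All randomness flows through explicit integer seeds; every
generator is a pure function of its arguments, and `scripts/acceptance.R`
re-derives the headline numbers from scratch against the installed package.

## Known limitations

* Tamura parameters (window cap, 16 bins, threshold 12, Prewitt masks) and
  the co-occurrence quantization (L = 16) follow the classic formulations;
  the source specifies none of them, so absolute feature values are
  convention-dependent even though all pipeline conclusions are.
* The greedy fitter explores far less of expression space than an
  evolutionary search; it spans the family of the published equations
  (degree ≤ 2 products by default, optional unaries and ratios) but will not
  discover, e.g., nested transcendentals.
* `read_texture()` reads PNG and TIFF natively; JPEG inputs must be
  converted first.
* Coarseness adapts its window cap on images smaller than 64 px, so its
  scale is comparable only across images of similar size.
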