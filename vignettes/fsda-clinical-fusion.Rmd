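---
title: "Discriminant reduction, clinical fusion and projection-aware CAMs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminant reduction, clinical fusion and projection-aware CAMs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fsdacam)
```

## The model and its assumptions

`fsdacam` targets binary classification of medical images in the regime
where a frozen pre-trained network supplies M-dimensional features
(M ~ 512–4096) and the dataset supplies N ≲ M labelled samples plus a
handful of clinical variables. Three assumptions underlie everything:

1. **Frozen features.** The backbone is a fixed map y = φ(I); no weights
   are trained. All supervision enters through the reduction and the
   classifier.
2. **Two classes, shared discriminative geometry.** The within-class
   scatter S_W = β·S_W1 + (1−β)·S_W2 with β = (N₂−1)/(N₁+N₂−2) summarizes
   both classes; the between-class structure is the rank-one
   S_B = s_b s_b′ with s_b = ȳ₁ − ȳ₂. Each per-class scatter S_Wj is the
   unbiased sample covariance (divisor Nⱼ−1); the source formulation
   never defines S_Wj, and this choice matches the (Nⱼ−1) factors inside
   β.
3. **Linear evidence.** Reduction (P), fusion (concatenation) and the CAM
   path (a single linear layer) are all linear, which is what makes the
   activation map exact rather than approximate: the spatial mean of the
   raw map *equals* the image-block contribution to the class score.

### The recursion

Because rank(S_B) = 1, classical binary LDA stops after
d₁ = α₁ S_W⁻¹ s_b. The Foley–Sammon construction continues: dₙ maximizes
the Rayleigh quotient R(d) = (s_b′d)²/(d′S_W d) subject to
d′dₖ = 0 (k < n), and has the closed recursive form implemented in
`next_direction()`, with the (n−1)×(n−1) Gram system
Sₙ₋₁[i,j] = dᵢ′S_W⁻¹dⱼ. Orthogonality holds *identically* in exact
arithmetic (the test suite checks 1e−8 numerically and also checks the
n = 2 step against the independent closed form, and d₁ against a dense
generalized-eigenvector oracle).

### The two within-scatter modes

As printed, the combination weights class 1's scatter by *class 2's*
count: β = (N₂−1)/(N₁+N₂−2). That is surprising — the classical pooled
covariance would use (N₁−1) there — and the two coincide exactly when
N₁ = N₂ (which holds for most of the balanced datasets the method was
demonstrated on). We implement the printed form as the default
(`within_mode = "as_printed"`) and expose `within_mode = "pooled"` for
the classical weighting, because we cannot rule out that the printed
form is intentional and fidelity costs nothing; the suite asserts both
the equality at N₁ = N₂ and the inequality away from it.

## Tunable parameters

| Parameter | Default | Units / range | Why this default |
|---|---|---|---|
| `L` | 10 | directions | the reduction size used throughout the protocol this package reproduces; also well below any fold's sample count |
| `ridge` | 1e−6·tr(S_W)/M | same units as feature variance | S_W is singular whenever M ≥ N; scaling by the mean feature variance makes the ridge dimensionless in effect |
| `within_mode` | `"as_printed"` | — | fidelity first; `"pooled"` one switch away |
| `folds` | 5 | — | the protocol's fivefold CV |
| classifier `kind` | `"margin"` | — | mirrors "SVM by default, fully connected for CAM" |
| margin `lambda` | grid {0.01, 0.1, 1} | penalty | searched by internal 3-fold CV *inside the training fold only* |
| RBF `gamma` | 1/median(‖zᵢ−zⱼ‖²) | inverse squared distance | standard median heuristic; deterministic |
| linear `lambda` | 0.01 | penalty | a mild ridge for a ≤ ~15-dimensional fused input |

Numeric clinical fields are z-scored on the training fold; categorical
fields are one-hot with the category set frozen at fit time. The
reduced image features are *not* rescaled — they are fused verbatim —
because the fusion equation concatenates P y directly; z-scoring the
clinical side is what keeps an age in tens from dwarfing reduced
features of order one (and vice versa).

## What the synthetic generator emulates — and what it does not

`gen_features()` draws class-conditional Gaussians sharing one
covariance (identity or random-SPD with a chosen condition number), with
a mean gap of `delta` within-class standard deviations on a few
informative dimensions. `gen_clinical()` emits one numeric and one
categorical variable whose association with the label is a single dial
(`clinical_effect`: 0 = independent, 1 = deterministic).
`gen_feature_maps()` plants a hot square (amplitude `snr` × noise sd) at
a class-dependent corner in class-specific channels and emits the
channel-wise GAP as the pooled features, so the CAM consistency contract
holds by construction, and ground-truth masks enable localization
scoring. Defaults (M = 512, a few informative dimensions, weak clinical
effect) mirror the ResNet18-sized small-sample regime.

What a green test on this world does **not** establish: real backbone
features are not Gaussian, their informative structure is not axis
-aligned or low-rank in any known basis, classes rarely share a
covariance, and real clinical variables are noisy, collinear with the
image signal, and missing-not-at-random. The generator supports the
*mechanics* (algebra, protocol hygiene, localization) — it cannot
certify clinical performance.

### The planted-blob localization scale

The localization criterion runs 100 independent end-to-end fits. The
scale was fixed once at: 30 samples per class, 16 channels, 4 hot
channels per class, 7×7 maps (the ResNet18 spatial size), 3×3 blob,
28×28 images, SNR 3 (the stated level). With class-specific hot
channels, GAP features separate the classes, the linear classifier
weights its own class's channels positively, and the back-projected map
concentrates on the blob; SNR 3 leaves enough per-pixel noise that the
hit rate is a meaningful statistic rather than a trivial one (the suite
measured 100% over the 200 test images of the 100 seeded fits, against a
required ≥ 90%).

## Numerical choices

* **Solves, not inverses.** Every S_W⁻¹ application is a Cholesky solve
  of the ridged scatter. The Gram system is solved densely ((n−1) ≤ L
  ≤ 10).
* **Sign convention.** Each direction is flipped so s_b′dₙ ≥ 0 (ties:
  first nonzero coordinate positive). Sign flips of later directions do
  not propagate into the recursion (the first direction's sign is fixed
  by construction), so the convention is purely cosmetic and makes runs
  platform-deterministic.
* **Truncation.** If the braced correction vector's norm falls below
  1e−10·‖s_b‖ the discriminative subspace is exhausted; `fit_basis()`
  truncates with a warning rather than emitting noise directions. With
  S_W ∝ I this happens immediately after d₁ = s_b/‖s_b‖ — with isotropic
  within-class scatter all discriminative information lies along s_b.
* **Round-off hygiene.** After each recursion step the new direction is
  re-orthogonalized against its predecessors (a no-op in exact
  arithmetic) so the 1e−8 orthonormality contract holds at any M.
* **Deterministic CAM arithmetic.** The raw map is accumulated channel
  by channel in a fixed order rather than through BLAS, so identical
  inputs give bit-identical maps across runs and match a reference
  channel-loop implementation exactly.
* **Interpolation.** Bilinear with corner-aligned sampling (constants
  preserved exactly, output range within input range); nearest-neighbour
  replicates cells exactly under integer upscaling. Display
  normalization is per-map min–max at render time only; negative
  evidence survives in `raw_map`.
* **Degenerate inputs.** Coincident class means → a typed
  no-direction error; a class with fewer than two samples → a typed
  degenerate-class error; constant maps normalize to zero with a
  warning; unknown categories encode to all-zeros.

## Design decisions that were genuinely open

* **Classifiers.** No SVM library is assumed. The margin classifier is a
  least-squares SVM (kernel ridge on ±1 targets with unpenalized bias):
  soft-margin, kernelizable, deterministic, and rotation-invariant with
  the RBF kernel — which the protocol's full-rank-rotation equivalence
  check requires. The linear classifier is ridge-penalized logistic
  regression exposed with the symmetric two-column weight matrix
  W = (−w, +w), so scores take the u = W′z + bias form the CAM
  derivation uses. The CAM uses weights only; the bias is used for
  prediction but never enters the map.
* **Embedding fusion.** The text-embedding strategy ships with a
  deterministic token-hashing embedder (two independent rolling hashes
  for position and sign). Heavyweight language-model embedders are
  deliberately out of the install path; the interface accepts any
  `function(text) -> numeric`.
* **AUC.** Rank-based (Mann–Whitney) on the positive class's continuous
  scores; decision values for the margin kind, no probability
  calibration. The positive class defaults to the second label in sort
  order and is recorded in the report.
* **PCA arm.** Training-fold centering always, unit-variance scaling
  optional (`pca_scale`), same L as the discriminant arm.
* **Leakage guard.** Reducers, encoders and hyperparameter search are
  fitted strictly inside each training fold. This is asserted by tests
  and has one substantive consequence, described next.

## The overwhelming-effect criterion stays red — analysis

One acceptance property asks that on pure-noise image features (M = 512)
with a single fully informative clinical variable (n = 100), the fused
discriminant arm beat the fused raw arm by more than 0.1 mean AUC. The
suite implements the check verbatim and it fails, by design of this
package rather than by accident:

* The overwhelming effect itself is real and reproduced: a perfect
  clinical feature among 10 iid noise columns yields CV AUC ≈ 1.0, among
  512 noise columns ≈ 0.76.
* But discriminant directions *fitted on pure noise* in the M ≫ N regime
  are not iid noise columns: they are selected to separate the training
  labels, and with M/N ≈ 6 they do so spuriously and almost perfectly.
  The downstream classifier, trained on the same fold, therefore trusts
  the 10 worthless image features as much as the perfect clinical one —
  the same tax the raw arm pays through its 512 dimensions — and the two
  fused arms tie (≈ 0.72–0.86 AUC, gap ≈ +0.01 over 20 repeats, for both
  classifier kinds and any regularization we tried).
* Fitting the basis on the *full* dataset before cross-validation (label
  leakage) restores the expected picture exactly — the fused
  discriminant arm reaches AUC 1.0 and the gap exceeds 0.3 — which is
  presumably the regime the expectation was calibrated in. We keep the
  leakage guard and the red test: a criterion that can only pass through
  leakage should not pass.

The practical reading for users: discriminant reduction helps when the
image features carry *some* true class structure (see the README's
worked example, where it dominates PCA and raw features); on genuinely
uninformative image features no fold-honest reduction can protect the
clinical signal, and the right model is the clinical variables alone.

## Known limitations

* Binary classes only; the multi-class generalization changes the
  between-scatter rank structure and is out of scope.
* Deep backbones are metadata-only specs here; in-process inference is
  limited to the synthetic backbone. Feature matrices extracted
  elsewhere are first-class inputs via the delimited-text reader.
* The CAM requires a convolutional feature map and the linear classifier
  kind; margin classifiers and transformer backbones without spatial
  maps are rejected with typed errors.
* The CAM never visualizes the clinical block's evidence (it has no
  spatial support); its scalar contribution is reported alongside the
  map instead.
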