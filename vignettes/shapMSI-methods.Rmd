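---
title: "Methods: classifier-based marker discovery with observational Shapley values"
author: "shapMSI"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: classifier-based marker discovery with observational Shapley values}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Imaging mass spectrometry (IMS) acquires a mass spectrum at every pixel of
a tissue section, yielding an intensity matrix $X \in \mathbb{R}^{m \times n}$
of $m$ pixels by $n$ peak-picked $m/z$ features. Given a user-drawn
annotation of one tissue class (an organ, a tissue region, a functional
unit), the marker-discovery question is: *which of the hundreds or
thousands of measured ion species are most characteristic of that class,
and where in the tissue do they carry that information?*

shapMSI answers it in two coupled steps:

1. **Classify.** Train a gradient-boosted regression-tree ensemble to
   recognise the class pixels from their spectra (one-versus-all).
2. **Explain.** Attribute every prediction exactly to the input features
   with observational (tree-path-dependent) Shapley values, rank features
   by the mean magnitude of their attributions, and map the attributions
   back onto the tissue as *SHAP maps*.

The classifier is a means to an end: a feature the classifier relies on,
at the pixels where it relies on it, is a candidate marker. Because the
explanation is exact (see *local accuracy* below), the ranking inherits
the fidelity of the model rather than adding its own approximation error.

## The classifier

The ensemble represents the log-odds of class membership additively:

$$ f(x) \;=\; \tau_0 + \nu \sum_{k=1}^{K} \tau_k(x), \qquad
   p(x) = \frac{1}{1 + e^{-f(x)}}, $$

with $\tau_0$ the training-set base-rate log-odds
$\ln(n_{pos}/n_{neg})$, $\nu$ the shrinkage (learning rate), and
$\tau_k$ regression trees. Training minimises the logistic negative
log-likelihood plus an L2 penalty $\lambda$ on leaf values by
second-order (Newton) boosting: with current probability $p_i$ and
target $t_i = (y_i+1)/2$, each round fits a tree to the gradients
$g_i = p_i - t_i$ and hessians $h_i = p_i(1-p_i)$ using exact greedy
split search with the usual gain
$\tfrac12 [ G_L^2/(H_L+\lambda) + G_R^2/(H_R+\lambda) - G^2/(H+\lambda)]$
and leaf values $-\sum g / (\sum h + \lambda)$. Stochasticity enters
through per-round row subsampling and per-node column subsampling.

Tunable parameters (see `trainingConfig()`), with defaults:

| parameter | default | meaning |
|---|---|---|
| `nTrees` (K) | 100 | boosting rounds |
| `maxDepth` | 4 | tree depth cap (interaction order) |
| `learningRate` ($\nu$) | 0.3 | shrinkage per tree, in (0,1) |
| `lambda` ($\lambda$) | 1 | L2 penalty on leaf values |
| `rowSubsample` | 0.8 | pixels drawn per round |
| `colSubsample` | 0.8 | features drawn per split node |
| `minChildCover` | 5 | minimum pixels per child node |
| `eta` ($\eta$) | 0.5 | probability threshold for class calls |

$\nu = 0.3$ and $\eta = 0.5$ are the conventional operating point for
boosted log-odds classifiers of IMS pixels; tree count, depth and
$\lambda$ are standard values exposed for tuning. A prediction is
positive when $p(x) \ge \eta$ (the tie goes to the positive class).

Annotation masks carry three codes: `POS`, `NEG` and `EXCLUDED`.
Excluded pixels (typically organ borders that cannot be annotated
reliably) never enter training or evaluation. Because the negative class
usually dwarfs the positive one, negatives are downsampled without
replacement so positives make up ~25% of the training pixels
(`downsampleNegatives()`), and performance is reported with
imbalance-aware metrics: precision, recall (sensitivity), specificity,
and balanced accuracy — the arithmetic mean of sensitivity and
specificity — on a stratified held-out split.

## Exact observational Shapley values

The Shapley value $\varphi_{ij}$ of feature $j$ at pixel $i$ is its
contribution to the raw output $f(x_i)$, averaged over all feature
orderings; equivalently a subset-weighted sum of marginal contributions

$$ \varphi_{ij} = \sum_{S \subseteq U \setminus \{j\}}
   \frac{|S|!\,(D-|S|-1)!}{D!}\,
   \bigl[ E[f(x_i)\,|\,S \cup \{j\}] - E[f(x_i)\,|\,S] \bigr]. $$

The conditional expectation is estimated *observationally* (tree-path
dependently): traversing a tree, a split on a feature in the coalition
$S$ follows the branch $x_i$ takes; a split on a feature outside $S$
averages both children weighted by their **cover**, the count of
training pixels routed through each child. This conditions on the
training distribution and spreads credit among correlated features,
which is the behaviour wanted for molecular data where many species move
together; *interventional* Shapley values (which break those
dependencies) are deliberately out of scope.

Attributions are computed on the raw log-odds margin, not the
probability, so they add exactly:

$$ f(x_i) = \varphi_0 + \sum_{j=1}^{n} \varphi_{ij}, \qquad
   \varphi_0 = E[f] \quad \text{(local accuracy)}. $$

`checkLocalAccuracy()` verifies this for every explained pixel; the test
suite requires it to hold within $10^{-6}$ (it holds to ~$10^{-14}$ in
practice).

Three independent routes compute the same quantity:

* `treeShapleySubsets()` — brute-force subset enumeration
  ($2^D$ expectations; refuses $D > 15$ distinct used features);
* `treeShapleyOrderings()` — the literal ordering average
  ($D!$ orderings; refuses $D > 8$);
* `treeShapleyPath()` — the polynomial-time path algorithm used in
  production (extend/unwind recurrences over per-path subset-cardinality
  weights), implemented in C++.

The two oracles exist purely to pin the path implementation down; the
suite sweeps hundreds of random trees with conserved random covers and
requires agreement to $10^{-9}$ (path vs subsets) and $10^{-12}$
(subsets vs orderings). The feasibility caps keep the oracle sweeps in
the seconds range. Attributions additionally agree with the
path-dependent TreeSHAP of an externally trained xgboost booster to
$10^{-4}$ (the residual is that implementation's float32 arithmetic).
Exactness also buys *consistency* (a feature whose influence on the
model grows never loses importance score), which therefore needs no
separate test, and the *dummy* property: a feature used by no tree gets
exactly zero everywhere.

The per-ensemble quantities follow by linearity:
$\varphi_{ij}(\text{ensemble}) = \nu \sum_k \varphi_{ij}(\tau_k)$ and
$\varphi_0 = \tau_0 + \nu \sum_k E[\tau_k]$. By default all pixels —
labeled or not — are explained (`ensembleShapley(..., pixels = NULL)`),
so the explanation spans the whole tissue; a `labeled_only` scope is
available for restricting to annotated pixels.

## Ranking and SHAP maps

The **global SHAP score** of feature $j$ is
$\Phi_j = \frac{1}{m}\sum_i |\varphi_{ij}|$, the mean absolute
attribution over the explained pixels. `rankFeatures()` sorts features
by descending $\Phi_j$, breaking ties by ascending $m/z$; the top of the
list is the candidate-marker shortlist.

A **SHAP map** (`shapMap()`) places one feature's $\varphi_{ij}$ on the
pixel grid. Its sign shows direction (positive: pushes the classifier
toward the class; negative: away), its magnitude shows strength.
Rendering (`renderDiverging()`) uses a symmetric diverging scale with
limits $\pm\max|\varphi|$ anchored at zero, so sign is never visually
distorted and equal saturations mean equal magnitudes; no spatial
smoothing is applied, because filtering would fabricate spatial
structure the model did not produce. The numeric scale limits accompany
each raster in a machine-readable sidecar JSON legend rather than being
burned into the bitmap, keeping the raster a pure function of the value
grid (and hence byte-reproducible).

The qualitative call a practitioner makes by eye — does high intensity
coincide with positive attribution? — is operationalised by
`directionCall()` as the Spearman rank correlation between a feature's
intensities and its Shapley values: above +0.3 is CORRELATIVE (presence
indicates the class), below −0.3 ANTICORRELATIVE (absence indicates the
class), otherwise INDETERMINATE. Rank correlation is used because
intensities are log-normally scaled; the ±0.3 threshold is a deliberate,
config-exposed convention wide enough to absorb attribution noise near
zero. Constant inputs or fewer than 10 pixels return INDETERMINATE
rather than a spurious sign.

## The phantom generator

Real IMS reference sets with per-pixel ground truth of marker identity
do not exist, so the package ships a generator whose outputs make every
downstream stage falsifiable. `phantomConfig()` draws

$$ X_{ij} = \exp\bigl( \mu + \Delta_{ij} + \sigma Z_{ij} \bigr), $$

log-normal intensities (multiplicative noise is the natural behaviour of
ion counts): baseline $\mu$, planted effects $\Delta$ (an UP marker adds
its effect size to the log intensity inside its region, DOWN subtracts
it), and Gaussian noise. Correlated feature pairs share a latent
Gaussian with configurable $\rho$; an optional artifact adds a fraction
of a marker's effect into a *bleed region* outside its home region,
emulating analyte delocalization during sample preparation. Per-region
one-versus-all masks label the region POS, everything else (other
regions and background) NEG, and exclude a 1-pixel boundary ring on both
sides of the region border — mirroring the practice of dropping
hard-to-annotate borders, with the width config-exposed.

The reference study conditions (`twoRegionPhantomConfig()`): a 32×32
grid, two rectangular regions, 50 features, five markers for region A
(three UP, two DOWN) with log-effect 2.0 (≈7.4-fold, a strong but
realistic tissue-specific lipid contrast) under $\sigma = 0.3$
(≈35% coefficient of variation, typical for peak-picked intensities).
The artifact variant (`artifactPhantomConfig()`) restructures the
markers so the confound is actually expressed: the affected marker is
the strongest effect (2.5) so the classifier leans on it and it leads
the ranking, the bleed deposits 90% of its effect — near-native
intensity, which is what makes a delocalization artifact confusable with
true signal — and two weaker clean markers (1.2) provide the spatially
specific signal that corrects the bleed pocket. With these conditions
the diagnostic pattern is reproduced: the affected marker's mean Shapley
value inside the bleed pocket is positive (it drags those pixels toward
the class) while the clean markers' is negative, which is exactly the
pattern a SHAP map shows and a global ranking hides.

What the phantom does **not** emulate: spatial autocorrelation of noise,
instrument drift across the raster, isotope envelopes and peak overlap,
matrix effects, or annotation errors beyond the excluded ring. Passing
the phantom suite therefore demonstrates correctness of the machinery
(training, exact attribution, ranking, mapping), not robustness to every
real-world acquisition pathology.

## Numerical and design choices

* **Routing convention.** `x[feature] <= threshold` goes left, at every
  node, identically in training, prediction and Shapley traversal — a
  single shared C++ routine. Mixing conventions would silently break
  local accuracy. Split thresholds are midpoints of adjacent observed
  values.
* **Cover semantics.** After each tree is grown on its row subsample,
  node covers are recomputed as counts over the *full* training set, so
  conditional expectations refer to the training distribution, not the
  round's subsample.
* **Imported boosters.** xgboost routes `x < threshold`; on import the
  threshold is snapped to float32 and stepped one float32 ulp down,
  making the two rules coincide for every float32-representable input.
  Imported covers are xgboost's hessian sums; the Shapley machinery only
  requires positive, conserved covers.
* **Determinism.** Every source of randomness flows from explicit seeds;
  the pipeline derives stage seeds from one master seed by a fixed
  affine map modulo a prime below $2^{31}$, and a rerun with the same
  configuration is byte-identical artifact for artifact.
* **Indexing.** The R API is 1-based throughout (pixels, features,
  nodes), as R users expect; the on-disk JSON schema and the grid
  coordinates are 0-based, as the interchange formats of the field are.
* **Model-quality floor.** An explanation is only as good as its
  underlying model, so `runDiscovery()` refuses to write a ranking when
  held-out balanced accuracy is below a floor (default 0.8), emitting a
  warning artifact instead.
* **Degenerate inputs.** All-zero SHAP maps render at a pinned ±1 scale;
  zero-denominator rates are reported as `NA` and propagate into an `NA`
  balanced accuracy; zero covers are a hard error.

## Problem sizes used by the test suite

The suite and the acceptance script run the reference phantom
(1,024 pixels × 50 features, 100 trees), 200 + 100 random trees for the
oracle sweeps, a 50-tree external booster on 200 pixels for the
cross-implementation check, and 10 independent replicates for marker
recovery and direction calls — sizes at which the full suite completes
in well under a minute on one CPU while still exercising every code
path at study-like dimensionality.

## Limitations

Exact observational Shapley values distribute credit among correlated
features; a correlated non-causal passenger feature can legitimately
receive non-zero attribution (that is the observational semantics, not a
bug). Rankings are relative to one trained model: different
hyperparameters can redistribute credit among near-redundant markers.
The direction call is a pixel-level monotone association summary;
region-level reading of ion image + SHAP map remains the user's
interpretive step, which `reportTopK()` supports but does not replace.
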