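---
title: "Evaluating deep generative models of breast phantom slices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evaluating deep generative models of breast phantom slices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Deep generative models (DGMs) trained on medical images are usually graded
with ensemble-level perceptual scores such as the Frechet Inception
Distance. Those scores can look excellent while the model quietly fails to
reproduce the image statistics that matter for the imaging task: tissue
intensity laws, morphology, the connectivity of fine structures, class
prevalence, or ensemble diversity. This package implements a
statistics-first evaluation framework for one well-controlled setting:
ensembles of 8-bit, 512x512 coronal slices of a procedurally generated
anthropomorphic breast phantom containing exactly four tissues — fat,
glandular tissue, skin and ligaments — in four BI-RADS-like breast classes
(fatty, scattered, heterogeneous, dense, prevalence 1:4:4:1). Because the
object model is fully known, every evaluation statistic has a known
expectation, and a candidate generator can be scored against them.

The package provides (i) a synthetic slice generator that emulates this
training distribution with known per-image ground truth, (ii) the
evaluation pipeline itself — a memorization screen and Frechet-distance
check followed by a bootstrapped Kolmogorov-Smirnov (KS) ranking metric in
feature principal-component space — and (iii) diagnostic analyses of class
structure, ensemble diversity and common generation artifacts.

## The phantom generator

`sample_layout()` builds a per-image tissue map procedurally:

* **Outline** — a superellipse with a low-order random radial perturbation
  and a mild egg asymmetry, guaranteed to be a single connected component
  and to stay inside the frame.
* **Skin** — all foreground pixels within 2-3 px of the background.
* **Ligaments** — the thinned edges of a Voronoi tessellation of
  Poisson-sampled interior seeds (default density 1.3e-3 seeds per interior
  pixel), giving 1-pixel-wide curves that partition the interior into
  bounded compartments, as ligaments do in the reference phantom.
* **Glandular tissue** — whole Voronoi compartments accreted around a
  random focus until the class target fraction g = G/(G+F) is reached; the
  final compartment is trimmed pixelwise so the achieved fraction matches
  the per-image target (drawn uniformly within the class band) to within
  0.05. Heterogeneous layouts additionally receive 2-4 spiculated "burst"
  stars of glandular spikes, the hallmark of that class.

The class bands default to fatty < 0.20, scattered 0.20-0.40, heterogeneous
0.40-0.65, dense >= 0.65. These bands are configuration, not constants: the
reference dataset never publishes them, so they were chosen once to span
the plausible BI-RADS glandularity range and are reused by the rule-based
classifier in the diagnostics module.

`assign_intensities()` renders a layout. Each tissue carries an
affine-scaled Beta law: fat `60 X + 52` with `X ~ Beta(2, 4)`, glandular
`96 X + 128` with `Beta(4, 2)`, skin `16 X + 228` and ligament `16 X + 232`
with `Beta(3, 3)`. A full-size field of Beta variates is drawn per tissue,
smoothed with a Gaussian filter (sigma = 0.8 px) to impose a short-range
texture, and then restored to the exact prescribed marginal by rank
matching against the analytic quantile function (sorted field values are
replaced by `offset + scale * qbeta((r - 0.5)/n, alpha, beta)`). The four
fields are masked by their exclusive tissue maps and summed; background is
exactly zero. Quantisation to 8 bits happens once, after summation, by
round-half-to-even with clipping to [0, 255]. Because the supports of the
four laws fall inside disjoint threshold bands, global thresholding can
recover the tissue maps essentially perfectly away from tissue boundaries.

What the generator does *not* emulate: the anatomy of real phantom slices
(vasculature and ducts replaced by glandular tissue in the reference data),
cross-slice correlation within one 3D phantom, and any imaging-system
degradation. Tests that pass on this generator therefore certify the
*evaluation machinery* — segmentation, features, metrics — under the
prescribed statistical structure, not anatomical realism.

## Segmentation

`segment_tissues()` thresholds at the printed band edges — background
`[0, 30)`, fat `[30, 120)`, glandular `[120, 226)`, high `[226, 255]` —
resolved half-open because the printed endpoints overlap. The foreground is
the largest connected component (floating specks are relabelled
background), and the shared skin/ligament band is split by location: high
pixels within 4 px of the foreground boundary are skin, the rest ligament.
The fat-glandular boundary mask used by the memorization measure is the
8-adjacency interface of the two tissues dilated by 2 px; the dilation
absorbs 1-pixel jitter so that near-copies still correlate strongly.

## The feature registry

`feature_registry()` enumerates 832 named scalar features in seven
families; the order is fixed and the name-vector hash is the registry
version stamped into every feature table and cache.

* **texture** (280) — symmetric, foreground-masked gray-level co-occurrence
  matrices at 64 gray levels, distances {1, 2, 4, 8} and angles {0, 45, 90,
  135} degrees; the 14 classical co-occurrence statistics per offset plus
  per-distance angular means.
* **intensity** (60) — first-order statistics per tissue and for the whole
  breast: area, mean, sd, min, max, quartiles, skewness, kurtosis,
  histogram energy and entropy. This family carries the nine features of
  the public metric (per-tissue areas and mean intensities plus the F/G
  ratio).
* **morphology** (238) — 14 shape properties per connected component of fat
  and glandular tissue (area, perimeter, convex-hull area/perimeter,
  solidity, convexity-perimeter ratio, eccentricity, axis lengths,
  orientation, extent, equivalent diameter, circularity, Euler number),
  summarised by the eight-statistic scheme, plus the whole-breast values.
* **skeleton** (43) — connected-skeleton count, endpoints, branch
  junctions, lengths, branch-segment lengths and the areas of the bounded
  compartments, for the (defensively re-thinned) ligament network.
* **fractal** (24) — box-counting dimension over dyadic box sizes 2..64 and
  gliding-box lacunarity per size, for fat, glandular and ligament masks.
* **moments** (186) — raw, central, normalised and Hu moments up to order
  3, binary and intensity-weighted, for fat, glandular and whole-breast
  scopes.
* **fg_ratio** (1) — fat over glandular pixel count.

Multi-valued features are summarised identically by {count, mean, sd, min,
max, Q1, Q2, Q3} with type-7 (linear-interpolation) quantiles. Missing
values (an empty tissue, a foreground smaller than a co-occurrence offset)
are explicit `NA`s; they are imputed with training-side column means only
at PCA time, so generated-ensemble statistics never leak into the model.

Numerical conventions worth knowing: perimeters are 8-connected outer
contour chain lengths (which overestimate smooth perimeters by a few
percent), convex hulls are computed on pixel corners so hull area bounds
pixel area and the convexity-perimeter ratio stays below 1 up to a
documented discretisation tolerance of 0.02; the lacunarity grid is
anchored at the mask bounding box with no offset averaging; adjacent
skeleton branch pixels are merged into single junctions.

## The two-stage evaluation

**Stage 1 (advisory screen).** The memorization measure of a generated
image is the maximum, over the training ensemble, of the zero-lag Pearson
correlation between flattened boundary masks; images above 0.9 are flagged.
The threshold can be re-derived on any training ensemble as `max + 1 sd` of
the measures of held-out training images scored against the remainder
(`calibrate_memorization_threshold()`). A 4x max-pooled prefilter keeps the
top 50 candidates per generated image before full-resolution rescoring;
tests verify the prefilter is exact against exhaustive search. The Frechet
distance `||mu1 - mu2||^2 + Tr(S1 + S2 - 2 (S1 S2)^{1/2})` is computed over
a pluggable embedder (the feature registry by default, a seeded random
pixel projection, or externally supplied vectors, e.g. from a pretrained
network); registry embeddings are standardised with training-side
statistics before the distance so that no single large-scale feature
dominates. A pass/fail line at 30 mirrors common screening practice,
though its meaning depends on the embedder and ensemble size; the verdict
is advisory, not an abort. The
matrix square root goes through the symmetric form `S1^{1/2} S2 S1^{1/2}`,
so no imaginary residue can arise.

**Stage 2 (ranking).** PCA is fitted on the training feature table
(training-mean imputation, z-scoring, zero-variance columns dropped and
recorded); both ensembles are projected to the top 10 components. Per
bootstrap replicate (1000 by default), images are resampled with
replacement on both sides, and two cosine-distance samples of 10,000 pairs
each are drawn — train-train (baseline) and train-generated (cross) — with
index pairs sampled without replacement and the diagonal excluded from the
baseline. The two-sample KS statistic between the distance distributions
is recorded; the mean over replicates is the ranking metric (lower is
better), with the sd as its uncertainty. Per-family sub-metrics rerun the
identical pipeline on one family's columns; the public metric restricts to
the nine public features.

Design choices the source material leaves open, decided here: features
*are* standardised before PCA (families live on wildly different scales);
imputation uses training means; baseline pairs exclude identical indices;
bootstrap resamples images, not distances. A property worth knowing: a pure
constant translation of the generated feature cloud saturates the metric
well below 1 (cosine distances from centred training points to a far offset
cloud still spread over the training side), so the metric's strength is
distribution *shape* changes; sensitivity tests therefore corrupt images,
not feature tables.

## Diagnostics

* **Class analyses** — a glandularity rule (`classify_by_glandularity()`,
  same bands as the generator) replaces a learned breast-type classifier;
  outputs carry that provenance. Class prevalence, and per-class k-NN
  density (fidelity) and coverage (diversity) in the top-2 PC space with
  k = 5, expected near 1 for an ensemble drawn from the training
  distribution; brute-force-verified on small instances. k = 5 was chosen
  once as the customary neighbourhood size for these manifold metrics.
* **Ensemble-mean semivariance** — the isotropic empirical semivariogram
  `gamma(h)` of the pixelwise mean image over the support where the mean
  exceeds a threshold; the sill is the mean of the last quartile of lags.
  An ergodic ensemble (pixel position carries no tissue identity) gives a
  flat, low sill; positional bias raises and tilts it. Because object sizes
  vary, the union-footprint edge always carries a smooth ramp; the
  `erode_px` argument (with a bulk-level support threshold) restricts the
  statistic to the interior, which is what the ergodicity tests use.
* **Artifact scan** — per image: breast-mask convexity-perimeter ratio with
  a < 0.9 boundary-break flag, disconnected-skeleton count and median
  bounded-region area (ligament breaks), and background statistics
  (fraction/mean/sd of nonzero background pixels). Ensemble level: a
  ligament-sticking score (mean pairwise correlation of ligament masks,
  near 1 when one ligament structure is replicated across images) and the
  glandular-mask lacunarity distribution over images classified
  heterogeneous (malformed "burst" patterns shift it), with training
  references attached when available. The rule-based class substitute
  selects a slightly different heterogeneous subset than a learned
  classifier would; this is noted, not reconciled.

## Problem sizes and reproducibility

All randomness flows through explicit integer seeds; seeded runs are
bit-reproducible, including written PNG bytes. The test suite exercises the
full pipeline on a 160-image ensemble at side 96 (chosen as the smallest
scale at which every class keeps enough images for per-class statistics),
plus one default-size 512 slice for the size contract; the acceptance
script regenerates 1200 images at side 128 and evaluates split-half
class-wise density and coverage with k = 5. Marginal-law KS checks read
pixels on a spaced lattice (every 4th row/column) because adjacent pixels
are *deliberately* correlated by the smoothing step; dequantisation jitter
makes the continuous-law test applicable to 8-bit values.

## Known limitations

* The generator reproduces the statistical structure the evaluation
  consumes, not phantom anatomy; its layouts are exchangeable across
  images, so cross-image correlations present in real slice stacks are
  absent.
* The per-class glandularity bands and the exact texture-feature
  enumeration are package choices where the reference material is silent;
  both are versioned configuration rather than hidden constants.
* The KS ranking metric is insensitive to pure translations of the feature
  cloud (see above) and, like any summary metric, to failures outside the
  registry's families.
* Flip/mirror artifact detection is out of scope.
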