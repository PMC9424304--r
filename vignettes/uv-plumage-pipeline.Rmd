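---
title: "Methods: quantifying UV plumage colouration from calibrated specimen images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying UV plumage colouration from calibrated specimen images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(uvplume)
```

Birds see into the ultraviolet, and many plumage colours carry UV components
invisible to us. Measuring UV colouration at scale means photographing
specimens with visible + UV camera channels, isolating the plumage from the
background, converting calibrated pixel values into the bird's own
(tetrachromatic) colour space, and modelling the resulting species-level
metrics on a phylogeny. `uvplume` implements that chain end to end, driven by
a synthetic-data generator so that every stage is verifiable without an image
archive: the generator knows each pixel's true reflectance spectrum, each
image's true plumage mask, and each simulated trait dataset's true
heritability and effect sizes, so the pipeline's outputs can be checked
against ground truth rather than eyeballed.

## The synthetic spectral world

Everything is computed on a 300–700 nm wavelength grid with a 5 nm step
(81 points); band integrals use the midpoint rule, which is exact for
quantities defined on the grid itself. `make_world()` supplies:

* a flat illuminant (idealised illumination);
* four receptor sensitivities of an average ultraviolet-sensitive (UVS)
  avian visual system — Gaussians peaked near u ≈ 370, s ≈ 445, m ≈ 508,
  l ≈ 565 nm, truncated to the grid and normalised to unit integral so a
  flat stimulus lands exactly on the achromatic null u = s = m = l = 0.25;
* five camera channel sensitivities: three visible channels behind a UV/IR
  cut filter (zero below 400 nm) and two UV channels behind a UV-pass filter
  transmitting 320–380 nm. There is deliberately no UV-range green channel:
  camera green responses in the UV are too weak to carry usable information,
  so the mapping basis never sees one.

A pixel's channel intensity is `gain × ∫ illuminant × reflectance ×
sensitivity dλ`, linear in both the lighting gain and the reflectance
spectrum; quantum catches use the same integral with receptor sensitivities,
and *relative* catches (u, s, m, l) divide by their sum. Parametric
reflectance spectra (`make_spectrum()`) cover the cases that matter for UV
metrics: flat greys, pure-UV Gaussian bumps confined to 300–400 nm,
carotenoid-like long-wavelength sigmoids, their "UV-yellow" sum, and
near-black `dark` materials (< 1% everywhere) for the photographic
background.

`make_specimen_image()` renders a bird (body, head, tail ellipses; optional
eye disc and label tag as non-plumage) above five grey standards of
2/40/60/80/99% nominal reflectance arranged left to right, every pixel
through the same forward model, plus optional Gaussian sensor noise. What the
generator does **not** emulate: plumage texture and patterning, specular
highlights, spatially varying illumination, chromatic aberration, or real
camera noise statistics. Tests passing on these synthetics therefore certify
the pipeline's *computational* correctness (each stage does what its
definition says, to stated tolerance); they do not certify robustness to
real-world imaging artefacts.

## Segmentation baselines and evaluation

Ground truth arrives as expert polygons in two classes, with non-plumage
polygons nested inside plumage ones (eyes, feet). Rasterisation uses a
pixel-centre point-in-polygon test (0-based coordinates, row 0 at top): a
pixel is plumage iff its centre is inside at least one plumage polygon and no
non-plumage polygon.

Two classic baselines are implemented with their published settings:

* **Modal thresholding.** Greyscale is the unweighted mean of the three
  visible channels rescaled to 0–255 integers (the underlying sources say
  only "converted to greyscale"); after Gaussian smoothing, pixels above the
  histogram mode plus an offset of 15 are foreground (histogram ties break
  toward the darker value, matching the dark-background assumption). Since
  the standards are inevitably segmented too, the most upper 8-connected
  component — minimum topmost row, ties by larger area — is kept: the
  specimen always sits above the standards.
* **Seeded region growing.** Breadth-first growth over 4-neighbours from
  each seed, admitting pixels whose grey value lies within
  [seed − 6, seed + 30] of the *initial* seed value (the published
  description leaves seed-value vs running-mean ambiguous; the initial value
  is used here and this choice is recorded). Seed regions are grown
  independently and unioned.

Both apply Gaussian smoothing first (separable convolution, reflective
borders — preserves constants and the image mean) and morphological
close-then-open with a 3×3 square element afterwards (closing fills holes,
opening removes speckle; the radius and connectivity conventions are not
specified upstream and are package choices). Chan–Vese and graph cut are
standard library algorithms and are not reimplemented; their initialisation
conventions are documented in the README for completeness.

Evaluation uses plumage-class pixel counts — true positives `p_ii`, false
negatives `p_ij`, false positives `p_ji` — with

* IOU = p_ii / (p_ii + p_ij + p_ji)
* precision = p_ii / (p_ii + p_ji)
* recall = p_ii / (p_ii + p_ij)

and the identity IOU = 1/(1/P + 1/R − 1) whenever all are defined. Undefined
metrics (empty prediction or truth) propagate as missing values with a
classed warning, never as 0, and are excluded from batch means with a
reported count. `mean_iou()` averages the two classes; batch summaries
report means (overall and per view group), minima, and fractions of images
above IOU/precision/recall 0.90/0.75/0.50.

## Colour extraction

**Grey-standard normalisation.** Per channel, nominal reflectances
(0.02…0.99) are regressed by OLS on the mean pixel intensity of each
standard region and the fitted line is applied to all pixels. The upstream
description defers the functional form to its calibration references; a
per-channel linear fit through the five standards is the simplest form that
(a) returns each standard to its nominal value on noise-free images and
(b) is exactly invariant to a global lighting gain. The intercept is kept
(the no-intercept variant is also gain-invariant; absolute values differ
slightly at the dark end, and the intercept absorbs any stray-light
pedestal). Standard means that fail to increase with nominal reflectance
raise an error rather than silently flipping the calibration.

**Cone-catch mapping.** Per receptor, OLS over the polynomial basis
{1, each channel, each squared channel, each pairwise product, each
three-way product of distinct channels} — 31 terms for 5 channels — maps
normalised channels to **raw** quantum catches; predictions are clipped at
zero and renormalised per pixel to give relative catches. Fitting raw
catches (rather than the ratio directly) keeps the target nearly linear in
the channels; on 250-spectrum calibration sets all four receptors fit with
R² > 0.99. Relative-catch accuracy is tight for plumage-typical spectra
(≥ 95% of image pixels within 0.02 of truth end-to-end on noise-free
synthetics) but degrades for very dim spectra, where the ratio amplifies
small absolute errors — the same regime the re-citing rule below removes
from analysis. Pixels whose raw catches are all non-positive are set to the
achromatic centre and counted.

**Low-reflectance re-citing.** Colour of nearly-black patches is
unreliable, so pixels with mean normalised reflectance strictly below 1%
across the five channels are re-cited to u = s = m = l = 0.25. The mean is
taken over all five channels (the upstream wording "across all channels"
names no list).

**Aggregation and sampling.** Specimens differ in pixel counts and single
pixels are noisy, so the plumage mask's bounding box is partitioned into
f×f blocks (anchored top-left, partial edge blocks allowed), a cell being
valid if it contains ≥ 1 plumage pixel and taking the mean of its plumage
pixels per channel. Candidate factors are enumerated from 100 down to 1 and
the first factor with ≥ 500 valid cells is chosen — i.e. the largest factor
that still returns 500 cells, giving maximal denoising. (Read literally,
"smallest factor in the range 100 to 1" would always choose 1 and make the
search pointless; the enumeration order resolves the wording.) 500 cells
are then sampled uniformly without replacement under the caller's seed;
masks with fewer than 500 cells return everything with a warning.
Aggregation operates on normalised channel values *before* cone-catch
mapping; the mapping is nonlinear, so the order matters and this choice is
deliberate (block-averaging camera data then mapping mirrors how a coarser
sensor would image the same scene).

## UV colouration metrics

Per specimen view, from the 500 sampled pixels:

* **mean u** — arithmetic mean of relative u; whole-plumage average UV.
* **peak u** — mean of the upper `ceil(fraction × n)` u values
  (default fraction 0.25; 0.50 and 0.10 as sensitivity settings);
  `peak_u(u, 1) ≡ mean_u(u)` and peak u is non-increasing in the fraction.
* **UV+ colouration** — a pixel is UV+ iff (1) its u quantum catch exceeds
  0.05 of a theoretical 100% white standard's u catch, (2) its UV-band
  (300–400 nm) reflectance exceeds 3%, and (3) its UV-band reflectance
  exceeds the minimum visible-band (400–700 nm) reflectance — so UV peaks
  count even when other wavelengths dominate (UV-yellow, UV-red). In camera
  space the UV band is the mean of the two normalised UV channels and the
  visible minimum the minimum of the three visible channels (the closest
  camera-space analogue of the spectral criteria; whether the original
  operationalisation worked on spectra or camera bands is not stated). The
  white reference is pushed through the same world/camera/mapping path as
  the pixels, keeping the ratio internally consistent. Criterion (3) uses a
  1e-9 epsilon guard so exact ties (a perfectly flat pixel) never flip on
  floating-point noise. A view shows UV+ colouration iff the flagged
  fraction strictly exceeds 5% of pixels (1% and 10% as sensitivity
  thresholds; strictness makes 25/500 absent and 26/500 present).

Species-level values per sex and view are arithmetic means of specimen
values; side views are dropped (their plumage is largely covered by back and
belly views). Presence flags aggregate by majority, with ties (e.g. one of
two specimens flagged) counting as present — the aggregation of binary flags
is not specified upstream and is a package decision.

## The phylogenetic mixed model

Species-level metrics are modelled as `y = Xβ + a + e` with phylogenetic
effects `a ~ N(0, σ²a A)` and residuals `e ~ N(0, σ²e I)`, where `A` is the
Brownian-motion correlation matrix of the tree scaled to unit height
(shared root-to-tip path lengths; diagonal 1). Continuous responses
(mean u, peak u) are log10-transformed then standardised; predictors are
standardised; binary presence/absence is left 0/1.

The sampler is a conjugate Gibbs scheme written for this package:

* flat improper prior on β; each variance gets a scaled inverse chi-square
  prior with scale V and degree of belief ν — equivalently
  inverse-gamma(ν/2, νV/2), the univariate reduction of the usual
  (V, ν) inverse-Wishart parameterisation, so the standard weakly
  informative choice V = 1, ν = 0.002 carries over unchanged;
* (β, a) are drawn **jointly** from their multivariate normal full
  conditional, by composition: β from its a-marginalised conditional
  (Woodbury identity in the eigenbasis of A), then a | β elementwise —
  an exact joint draw costing O(q) per iteration after one eigendecomposition
  of A, rather than O((n+p)³) per iteration for the naive joint update;
* variances from their inverse-gamma full conditionals (either can be held
  fixed); a 1e-8 floor on A's eigenvalues guards near-singular trees.

The eigenbasis trick requires a balanced design — every species contributing
the same number of rows (one for species-level data; four for the
species × sex × view layout, where sex and view enter as fixed effects and
the four rows share one phylogenetic effect). Unbalanced designs are
refused with an explicit error rather than silently falling back to a slow
path.

Binary responses use **probit data augmentation**: a latent
`z ~ N(Xβ + a, 1)` truncated to the observed side is drawn each iteration
and the gaussian machinery runs on z with σ²e fixed at 1. The original
analyses used a logit-based "categorical" family; probit gives exact
conjugacy at desk scale. Effect directions and significance are comparable;
coefficient magnitudes sit on the probit scale and are not directly
comparable to logit estimates. Complete separation (a predictor perfectly
splitting the response) triggers a warning, as the corresponding coefficient
is then unidentified.

Downstream quantities are computed per draw and summarised by posterior
medians with 95% credible intervals: phylogenetic heritability
H² = σ²a/(σ²a + σ²e) from intercept-only fits; marginal
R² = var(Xβ)/(var(Xβ) + σ²a + σ²e) and conditional
R² = (var(Xβ) + σ²a)/(var(Xβ) + σ²a + σ²e). Fits over a distribution of
trees are pooled by concatenating draws (tree ids retained), so pooled
intervals absorb phylogenetic uncertainty; pooling is order-invariant.

**Chain settings.** The full-scale analysis convention is 110,000
iterations, thinning 25, burn-in 10,000, run over 100 trees. This package's
default is one tenth of that — 11,000 / 25 / 1,000, i.e. 400 retained draws
per tree — which the recovery studies below show is ample at the problem
sizes the package simulates; the full settings remain available through
`chain_settings()`.

## Simulation scale and what the checks show

Problem sizes used throughout the tests and analysis scripts, chosen so a
complete run stays interactive on a laptop: 90×150-pixel images (≈ 1,600
plumage pixels), 250-spectrum calibration sets, 150–300 species trees,
11,000-iteration chains, 20-replicate recovery studies. At these sizes:

* the sampler's β marginal matches the closed-form conjugate regression
  posterior (Student t) when A is inert, with Kolmogorov–Smirnov distance
  < 0.05 on 10,000 draws;
* H² recovery at 200 tips is unbiased but noisy: the posterior median
  tracks an independent ML profile-likelihood estimate at r ≈ 0.999, and
  the spread of both around the generating value is the information limit
  of a single realisation on one tree — roughly ±0.1–0.2 for mid-range H².
  Recovery-style checks should therefore be read as calibration statements
  about the estimator, not guarantees about single datasets;
* the probit sampler with an inert A matches an independently written plain
  probit data-augmentation sampler.

## Known limitations

* The generator's geometric specimens make thresholding look better than it
  is on real museum photographs (dark birds and prominent labels are the
  documented failure modes of classic methods; deep-learning segmentation,
  which addresses them, is out of scope here).
* The balanced-design restriction of the sampler excludes species with
  missing sex × view combinations; real datasets would need completion or a
  general (slower) solver.
* The probit/logit scale difference means binary-model coefficients are
  comparable across this package's own fits only.
* Relative cone catches for very dim (sub-1%) pixels are intrinsically
  ill-determined; the re-citing rule removes them by design rather than
  pretending accuracy.
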