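---
title: "Methods: quantifying myocardial scar in two-channel nonlinear microscopy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying myocardial scar in two-channel nonlinear microscopy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

This vignette is the package's own account of its models and of the design
choices behind them.  It states no empirical result that the test suite or
`scripts/acceptance.R` does not itself compute.

## The measurement problem

Healing after myocardial infarction replaces muscle with collagen-rich
scar.  Two-channel nonlinear optical microscopy separates the two tissue
components without staining: second harmonic generation (SHG) is specific
to fibrillar collagen, and two-photon excited fluorescence (TPEF) reports
the endogenous fluorophores of cardiomyocytes.  The package quantifies
co-registered SHG/TPEF frame pairs in three ways — collagen amount, fiber
morphology, and orientation statistics ("conventional" features), plus an
IBSI-style radiomic panel — and classifies each frame as healthy muscle,
infarct border, or mature fibrosis with a Monte-Carlo stacked ensemble.

No public dataset of this kind exists, so the package is validated end to
end on a synthetic fibrous-tissue generator with known ground truth.

## The synthetic generator

Each tissue phenotype is a parameter set: collagen fiber count, truncated
normal length and width distributions (µm), an axial orientation model,
waviness, per-channel intensity scales, background and noise levels.
Orientation is axial data (a fiber at θ is the same fiber at θ + 180°), so
directions are drawn by the doubled-angle construction: a von Mises draw
with concentration κ around 2µ on the full circle, halved back into
[0°, 180°).  κ = 0 gives an isotropic field; κ is directly interpretable
as axial concentration.  Waviness w ∈ [0, 1] makes the centerline heading
oscillate sinusoidally with amplitude wπ/2, so chord/arc straightness
decreases monotonically in w (for a full period the expected straightness
is the Bessel ratio J₀(wπ/2)).

Fibers are rendered as additive ridges with Gaussian cross-section whose
full width at half maximum equals the fiber width; rendering two fibers
equals the sum of their individual renderings, which the tests exploit as
an oracle.  Channels receive Poisson shot noise plus Gaussian read noise
and are clipped to a ~10-bit signal range inside the 16-bit container,
emulating detector saturation.  The clip also keeps the TPEF histogram
bimodal — without it the lognormal spread of rendered peak intensities
gives a long-tailed histogram on which a maximum-entropy threshold
retains only the brightest pixels, which no real myocardium image shows.

The three presets encode the qualitative class contrasts: muscle is
TPEF-dominant with long parallel myofibers and sparse thin collagen
(collagen intensity ratio near 0.1); border has more numerous, longer,
thicker, interlaced collagen among disordered myocardium (ratio near 0.3);
fibrosis is an SHG-dominant mesh of thick wavy collagen with sparse
amorphous TPEF.  Counts are calibrated for a 512 px field and scale with
area at other sizes.  Datasets are organized as ROI "depth stacks" with
per-ROI multiplicative parameter jitter (batch structure), and ROIs
alternate between two pseudo-subjects so train/test splits can be
segregated by subject, as an animal study would be.

What the generator does **not** emulate: optical point-spread functions,
depth-dependent attenuation, true myocyte texture (myocardium is rendered
with the same ridge primitive as collagen), or the physiological coupling
between collagen and myocardium orientation fields.  Passing tests
therefore demonstrate that the measurement pipeline recovers known
structure from images with realistic noise and class contrast — not that
it would reach any particular accuracy on ovine tissue.

## Preprocessing

**Frangi vesselness.**  Collagen ridges are enhanced with the standard
2-D Hessian-eigenvalue filter at scales σ = 1.8, 4.9, 8 px (Gaussian
derivative kernels, scale-normalized by σ²; the scales may alternatively
be read as kernel diameters via a flag).  With |λ₁| ≤ |λ₂|, blobness
R_b = λ₁/λ₂ and structure norm S = √(λ₁² + λ₂²) give the bright-ridge
response exp(−R_b²/2β²)(1 − exp(−S²/2c²)), zero wherever λ₂ ≥ 0; the
output is the maximum over scales.  β = 0.5.  Two numerical choices
matter:

* the second-derivative kernels are explicitly zero-meaned, so flat
  regions give an exactly zero Hessian despite kernel truncation;
* the automatic `c` is **half the maximum structure norm over the whole
  ROI stack and all scales**, not per frame or per scale.  Per-scale
  auto-`c` equalizes coarse scales and inflates ridge footprints (a 4 px
  fiber segments ~15 px wide); per-frame auto-`c` lets a frame of pure
  noise normalize its own noise to full response.  Stack-level `c` is the
  original single-constant recipe and keeps a zero-collagen frame in a
  mixed stack below 2% segmented pixels.

**Thresholds.**  The maximum Rényi-entropy threshold maximizes the sum of
Rényi entropies of the sub- and supra-threshold distributions; order 1 is
the Shannon/Kapur limit and is the default (the order is configurable).
The Li threshold minimizes the cross-entropy criterion
η(t) = −Σ_{g≤t} g·h(g)·log μ_b − Σ_{g>t} g·h(g)·log μ_f.  The classical
fixed-point iteration is only a local optimizer of η: on multimodal
histograms it settled up to 8 levels away from the global minimum, so the
package minimizes η by exhaustive scan over the (at most a few hundred)
candidate levels, which is exact, equally fast, and trivially independent
of initialization.  Segmentation thresholds are always computed from the
pooled ROI-stack histogram and shared by all frames of the stack.  The
SHG path is Frangi → 16-bit stack rescale → stack Rényi threshold; the
TPEF path is 8-bit stack rescale → stack Rényi threshold.  Foreground
masks for radiomics OR the per-channel Li masks.  Requantization rounds
half away from zero.

## Conventional features

The 16 features are: the intensity ratio C_I = mean(SHG)/(mean(SHG) +
mean(TPEF)); the segmentation ratio C_S on binary masks; fiber count,
mean/SD of fiber length, width, and straightness; MVL and range of the
fiber-angle histogram; MVL and range of the SHG and TPEF image
orientation histograms; and the SHG–TPEF mean-angle mismatch.

**Fiber tracer.**  A skeleton-based stand-in for curvelet fiber
extractors: Zhang–Suen thinning, junction detection by ring crossing
number (robust on diagonal staircases, unlike a raw neighbor count),
branch splitting, greedy merging of branches that continue within 30° of
straight across a junction, and pruning below 15 px.  The ordered
centerline is smoothed with a 5-point moving average before arc-length
measurement, because raster-skeleton staircase jitter otherwise inflates
arc length by ~20% and deflates straightness accordingly.  Width is twice
the mean distance-transform value along the centerline of the
half-maximum footprint of the enhanced ridge (minus a 0.5 px
discretization offset); the pipeline binary itself is not used for width
because the stack-level entropy threshold deliberately keeps faint
collagen and therefore loose footprints.  Recovery is verified on
rendered ground truth: length within 15%, width within 1 px at the
3–6 px widths the presets produce, semicircular-arc straightness within
0.05 of 2/π.

**Directionality.**  The Hann-windowed power spectrum is binned by
orientation into 1° bins over [0°, 180°): spectral energy at frequency
angle φ belongs to image structures at φ + 90°.  Frequencies below ~1.5
cycles per image (window leakage) and above Nyquist are excluded.

**Circular statistics.**  The mean vector is computed literally as
(X̄, Ȳ) = (Σ f(θ)cos θ, Σ f(θ)sin θ) over bin centers in [0, π) — **no
angle doubling** — to reproduce the statistic as printed in the source
formulation.  Under this form a uniform axial histogram has MVL
≈ 0.6366 (2/π in the continuum), not 0, and the statistic is not
rotation-equivariant for histograms straddling the 0/π wrap point.  A
doubled-angle MVL (`mvl_axial`), the standard axial concentration measure
that is 0 for uniform data and exactly rotation-equivariant, is returned
as a separate diagnostic.  The range R is the length of the shortest
circularly contiguous run of bins whose summed weight strictly exceeds
1/2, found by exhaustive scan with wraparound; "strictly exceeds" carries
a 1e−12 guard so floating-point ties (a 90-bin window of a uniform
histogram sums to exactly 1/2) resolve to the mathematically correct 91
bins.  Ties are broken by the shorter arc, then the smaller start angle.
The mean angle is atan2(Ȳ, X̄) mapped to [0, π); the SHG–TPEF mismatch
uses the axial distance min(d, π − d) ∈ [0, π/2].

## Radiomics

Inputs are 4×4-binned (512→128 px), Li-OR-masked, background-renormalized
frames, rescaled to 0..255 with dataset-wide per-modality extrema.
Gray values enter texture formulas 1-based (g = level + 1) so
low-gray-level emphases are finite; Ng = 256 in normalized
inverse-difference weights; directional families (GLCM distance 1, GLRLM)
average features over the four 2-D directions; GLSZM zones and NGLDM
dependences use 8-connectivity (α = 0); NGTDM uses masked 8-neighbor
means.  The 2-D morphology family reinterprets volume as area and surface
as perimeter; `morph.com` is the centroid–weighted-centroid distance, and
the global intensity peak uses a 3 px radius.  Degenerate single-level
regions yield flagged missing values (NA), never silent zeros — a zero
would quietly distort the KDE screening and the ensemble.  Zone labeling
runs over all gray levels simultaneously by min-label propagation with
pointer jumping, which the tests verify against per-level flood fill.
Every feature of every family is additionally verified against an
independent loop-written brute-force implementation at 1e−9 relative
tolerance.

## Screening, statistics, classification

**KDE overlap.**  Per feature, Gaussian KDEs of the training and test
values (Sheather–Jones bandwidth, Silverman fallback; SJ is the
solve-the-equation selector available in base R) are evaluated on a
shared 2048-point grid spanning both ranges padded by 5 bandwidths, and
the overlap is the trapezoid integral of their pointwise minimum.  The
5-bandwidth padding keeps truncated-tail error below 1e−6 so identical
samples overlap at 1 within tolerance.  Features below 0.75 overlap are
discarded as batch-affected; only radiomic features are screened.

**Tests.**  Kruskal–Wallis (tie-corrected, χ² reference) across the three
classes and a two-sided Wilcoxon rank-sum for muscle vs pathological;
exact enumeration for small untied samples, normal approximation with tie
correction otherwise; raw p < 0.05, no multiplicity correction (an
adjustment can be applied downstream if desired).  Completely tied data
return H = 0, p = 1.  Radiomics are related to conventional features by a
pairwise-complete Pearson matrix.

**Ensemble.**  Monte-Carlo folds draw a class-balanced validate set
(equal per-class counts totalling ~20%, floored to feasibility), leaving
the training split imbalanced.  Entirely inside each fold: median
imputation, [0, 1] range normalization from training statistics,
redundancy reduction (drop the later of any pair with |r| > 0.95),
univariate Kruskal–Wallis selection to the top 12, minority upsampling by
convex interpolation between same-class pairs, three heterogeneous base
learners (linear-kernel SVM, 200-tree random forest, 5-NN
class-probability rule), and a multinomial meta-learner trained on
out-of-fold base predictions (5 stratified inner folds).  Feature weights
are normalized permutation importances of the full stack, averaged across
folds; dropped features weigh zero.  Test-set inference aggregates fold
models by majority vote.  The whole fit runs under a derived seed because
the SVM's probability calibration draws from the global RNG.  Leakage is
tested directly: perturbing a validate-only row changes nothing in the
fitted fold.

## Problem sizes and benchmark

The default study layout is 3 classes × 2 pseudo-subjects × 2 ROIs each ×
15 frames = 180 frames; the package runs it at 256 px frames with 20
Monte-Carlo folds, the problem size chosen for the routine test suite and
the acceptance script (the generator's default frame size remains 512 px,
the acquisition geometry).  On this layout the suite requires ≥ 90% mean
cross-validation accuracy, ≥ 85% subject-held-out binary accuracy, and a
label-permutation control within Monte-Carlo noise of 1/3 — artifact
acceptance thresholds for the well-separated synthetic presets, not
claims about real tissue.

## Known limitations

* The fiber tracer is a skeleton-based stand-in, not a curvelet method;
  on dense meshes it merges or fragments crossing fibers more readily.
* The literal (non-doubled) MVL compresses differences between strongly
  concentrated orientation fields; the doubled-angle diagnostic is the
  better concentration measure and is provided alongside.
* Paper-scale class-mean values and accuracies from the original ovine
  study are not reproducible from synthetic data and are not targets
  anywhere in the package.
* The ensemble is a transparent stand-in for a proprietary AutoML
  protocol; no claim of equivalence is made.
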