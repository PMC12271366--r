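# nlomscar

Quantitative analysis of myocardial scar tissue in two-channel nonlinear
optical microscopy.  After a myocardial infarction, healing replaces
contractile muscle with collagen-rich scar; label-free nonlinear microscopy
images this process with two complementary channels — second harmonic
generation (SHG), specific to fibrillar collagen, and two-photon excited
fluorescence (TPEF) from the endogenous fluorophores of cardiomyocytes.
`nlomscar` implements an end-to-end pipeline that classifies imaged tissue
into three histological classes (healthy **muscle**, infarct **border**,
mature **fibrosis**) from such image pairs, for image-analysis researchers
who want a fully testable, self-contained reference implementation: because
no public two-channel dataset of this kind exists, the package ships a
synthetic fibrous-tissue generator with per-fiber ground truth, and every
stage is validated against it.

## What the pipeline computes

1. **Synthetic data** — labeled two-channel frames rendered from tissue
   phenotypes (fiber counts, length/width distributions, axial von Mises
   orientation concentration on doubled angles, waviness, intensities),
   with Poisson shot noise and Gaussian read noise, organized as ROI depth
   stacks split over two pseudo-subjects.
2. **Preprocessing** — multiscale Frangi vesselness for collagen ridge
   enhancement; stack-level linear requantization; maximum Rényi-entropy
   (Kapur) and Li minimum-cross-entropy thresholds; Li-OR foreground masks;
   4×4 binning; background renormalization.
3. **16 conventional features** — collagen amount
   (`C_I = mean(SHG) / (mean(SHG) + mean(TPEF))`, the analogous segmented
   ratio `C_S`), skeleton-based fiber morphology (count, length, width,
   straightness), and directionality: Fourier-spectrum orientation
   histograms `f(θ)` over 1° bins with circular statistics — the mean
   vector `(X̄, Ȳ) = (Σ f cos θ, Σ f sin θ)`, its length
   `MVL = √(X̄² + Ȳ²)`, the range `R` (shortest arc holding more than half
   the weight), and the SHG–TPEF mean-angle mismatch.
4. **Radiomics** — an IBSI-style 2-D panel per modality (intensity,
   histogram, intensity-volume histogram, morphology, GLCM, GLRLM, GLSZM,
   NGTDM, NGLDM; 122 features × 2 modalities), every feature backed by a
   brute-force oracle test.
5. **Harmonization & statistics** — per-feature kernel-density overlap
   between the training and test subjects with a 0.75 screening threshold;
   Kruskal–Wallis and Wilcoxon rank-sum tests; the radiomics-vs-conventional
   Pearson matrix.
6. **Classification** — 100-fold-style Monte-Carlo train/validate splits
   with class-balanced validation, in-fold preprocessing (range
   normalization, redundancy reduction, rank-test feature selection,
   synthetic minority interpolation), a two-layer stacked ensemble
   (linear SVM + random forest + k-NN, multinomial meta-learner on
   out-of-fold predictions), permutation feature weights, and
   confusion-matrix analytics with the border/fibrosis →
   "pathological" binary collapse.

## Worked example

```r
library(nlomscar)

## one synthetic fibrosis frame with ground truth
ph  <- phenotype_presets()$fibrosis
img <- generate_image(ph, size_px = 256, seed = 42)

## conventional features for this frame
seg_s <- segment_collagen_pipeline(list(img$shg))
seg_t <- segment_tpef_pipeline(list(img$tpef))
fib   <- trace_fibers(seg_s$binary[[1]], seg_s$enhanced[[1]])
conventional_feature_vector(img$shg, img$tpef,
                            seg_s$binary[[1]], seg_t$binary[[1]], fib)
```

The vector contains the 16 named features; on this frame
`collagen.intensity = 0.354` (a third of the signal is collagen, against
about 0.10 for muscle presets), `collagen.segmentation = 0.493`, and 11
fibers are traced with mean length 24.2 µm and mean width 3.4 µm.

The full study runs as four numbered drivers:

```sh
Rscript analysis/01_simulate.R --seed 1      # 180 frames, 12 ROI TIFF stacks
Rscript analysis/02_extract_features.R       # 16 + 244 features per frame
Rscript analysis/03_screen_stats.R           # KDE screening, tests, Pearson
Rscript analysis/04_classify.R --seed 1      # Monte-Carlo stacked ensemble
```

With seed 1 this prints: 189 of 244 radiomic features kept at KDE overlap
≥ 0.75; 16 of 16 conventional features significant in the three-class
Kruskal–Wallis test; cross-validation accuracy 100 ± 0 %, held-out-subject
three-class accuracy 92.2 % and binary (healthy vs pathological) accuracy
100 %.  The synthetic classes are deliberately well separated, so these
accuracies characterize the pipeline's correctness, not expected
performance on real tissue.

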