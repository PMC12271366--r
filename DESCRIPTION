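Package: nlomscar
Title: Quantitative Analysis of Myocardial Scar in Two-Channel Nonlinear
    Optical Microscopy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end quantitative analysis of two-channel nonlinear
    optical microscopy images of cardiac tissue, where a second-harmonic
    generation (SHG) channel reports fibrillar collagen and a two-photon
    excited fluorescence (TPEF) channel reports myocardium.  Provides a
    synthetic fibrous-tissue image generator with ground truth for three
    tissue phenotypes (healthy muscle, infarct border, mature fibrosis);
    image preprocessing (multiscale Frangi vesselness enhancement,
    Renyi/Kapur maximum-entropy and Li minimum-cross-entropy thresholding,
    binning, background renormalization); sixteen conventional imaging
    features covering collagen amount, skeleton-based fiber morphology and
    Fourier-spectrum directionality with circular statistics; a 2-D
    IBSI-style radiomic feature panel (intensity, histogram,
    intensity-volume histogram, morphology, GLCM, GLRLM, GLSZM, NGTDM,
    NGLDM); kernel-density-overlap feature screening between train and
    test sets; nonparametric group statistics; and a Monte-Carlo
    stacked-ensemble classifier of tissue class with permutation feature
    weights and confusion-matrix analytics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    EBImage,
    e1071,
    jsonlite,
    nnet,
    ranger,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
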