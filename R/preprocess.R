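## Image conditioning: multiscale Frangi vesselness, maximum-entropy and
## minimum-cross-entropy thresholding, foreground masks, binning and
## background renormalization.

gaussian_hessian_kernels <- function(sigma) {
  r <- max(1L, ceiling(3 * sigma))
  x <- outer(rep(1, 2 * r + 1), -r:r)
  y <- t(x)
  g <- exp(-(x^2 + y^2) / (2 * sigma^2)) / (2 * pi * sigma^2)
  gxx <- (x^2 / sigma^4 - 1 / sigma^2) * g
  gyy <- (y^2 / sigma^4 - 1 / sigma^2) * g
  ## zero the (truncation-induced) DC response so flat regions give a
  ## strictly zero Hessian
  gxx <- gxx - mean(gxx)
  gyy <- gyy - mean(gyy)
  list(gxx = gxx, gyy = gyy, gxy = (x * y / sigma^4) * g)
}

#' Multiscale Frangi vesselness for bright ridges
#'
#' Enhances tubular/fibrous structures (collagen on a dark background).  At
#' each scale the image is convolved with scale-normalized Gaussian
#' second-derivative kernels; the Hessian eigenvalues `l1, l2`
#' (`|l1| <= |l2|`) yield the blobness ratio `Rb = l1/l2` and structure
#' norm `S = sqrt(l1^2 + l2^2)`, and the response is
#' `exp(-Rb^2 / (2 beta^2)) * (1 - exp(-S^2 / (2 c^2)))`, zeroed where
#' `l2 >= 0` (dark or flat structures).  The output is the maximum over
#' scales and is nonnegative.
#'
#' @param image 2-D numeric matrix.
#' @param scales_px Gaussian standard deviations in pixels (set
#'   `scale_is_diameter = TRUE` to pass kernel diameters instead).
#' @param beta blobness sensitivity (default 0.5).
#' @param c_mode `"auto"` sets `c` to half the maximum structure norm over
#'   all scales (so the best-matching scale dominates and coarse scales do
#'   not inflate ridge footprints); a numeric value fixes it.
#' @param scale_is_diameter interpret `scales_px` as diameters (`sigma =
#'   scale / 2`).
#' @return nonnegative matrix of the same shape.
#' @export
frangi_vesselness <- function(image, scales_px = c(1.8, 4.9, 8),
                              beta = 0.5, c_mode = "auto",
                              scale_is_diameter = FALSE) {
  per_scale <- frangi_core(image, scales_px, beta, scale_is_diameter)
  smax <- max(vapply(per_scale, function(ps) max(ps$s), 0))
  cpar <- if (identical(c_mode, "auto")) smax / 2 else as.numeric(c_mode)
  frangi_combine(per_scale, cpar, dim(image),
                 noise_floor = 1e-9 * max(abs(image), 1))
}

## per-scale Hessian analysis: blobness factor and structure norm
frangi_core <- function(image, scales_px, beta, scale_is_diameter) {
  if (length(dim(image)) != 2) stop2("image must be 2-D")
  if (length(scales_px) == 0) stop2("at least one scale is required")
  sigmas <- if (scale_is_diameter) scales_px / 2 else scales_px
  if (any(sigmas < 0.5)) stop2("scales below 0.5 px are rejected")
  nr <- nrow(image); nc <- ncol(image)
  per_scale <- vector("list", length(sigmas))
  for (si in seq_along(sigmas)) {
    sigma <- sigmas[si]
    k <- gaussian_hessian_kernels(sigma)
    s2 <- sigma^2
    ## replicate-pad once, then convolve with cheap circular boundary
    r <- (nrow(k$gxx) - 1L) %/% 2L
    ri <- c(rep(1L, r), seq_len(nr), rep(nr, r))
    ci <- c(rep(1L, r), seq_len(nc), rep(nc, r))
    padded <- image[ri, ci]
    keep_r <- r + seq_len(nr); keep_c <- r + seq_len(nc)
    conv <- function(kern)
      EBImage::filter2(padded, kern, boundary = "circular")[keep_r, keep_c]
    a <- s2 * conv(k$gxx)
    b <- s2 * conv(k$gxy)
    d <- s2 * conv(k$gyy)
    tmp <- sqrt(((a - d) / 2)^2 + b^2)
    h1 <- (a + d) / 2 + tmp
    h2 <- (a + d) / 2 - tmp
    swap <- abs(h1) > abs(h2)
    l2 <- h2; l2[swap] <- h1[swap]   # larger magnitude
    l1 <- h1; l1[swap] <- h2[swap]
    s <- sqrt(l1^2 + l2^2)
    rb2 <- (l1 / l2)^2
    rb2[!is.finite(rb2)] <- 0
    blob <- exp(-rb2 / (2 * beta^2))
    blob[l2 >= 0] <- 0
    per_scale[[si]] <- list(blob = blob, s = s)
  }
  per_scale
}

frangi_combine <- function(per_scale, cpar, dims, noise_floor = 0) {
  out <- matrix(0, dims[1], dims[2])
  ## a structure norm at float-noise level means no structure at all
  if (cpar <= noise_floor) return(out)
  for (ps in per_scale) {
    v <- ps$blob * (1 - exp(-ps$s^2 / (2 * cpar^2)))
    out <- pmax(out, v)
  }
  out
}

check_histogram <- function(counts) {
  if (any(counts < 0)) stop2("histogram counts must be nonnegative")
  if (sum(counts > 0) < 2)
    stop2("degenerate histogram: fewer than 2 occupied levels")
}

#' Maximum Renyi entropy threshold
#'
#' Returns the level `t` (on the 0-based level scale of the histogram)
#' maximizing the sum of Renyi entropies of the below-threshold and
#' above-threshold normalized distributions.  Order 1 is the Shannon limit
#' (Kapur's maximum-entropy threshold).  Foreground is `level > t`.
#'
#' @param counts histogram counts for levels `0 .. length(counts) - 1`.
#' @param renyi_order entropy order, > 0.
#' @return integer threshold level.
#' @export
max_entropy_threshold <- function(counts, renyi_order = 1) {
  check_histogram(counts)
  if (renyi_order <= 0) stop2("renyi_order must be > 0")
  p <- counts / sum(counts)
  n <- length(p)
  pb <- cumsum(p)
  pa <- 1 - pb
  valid <- which(pb > 0 & pa > 0)
  valid <- valid[valid < n]
  if (length(valid) == 0) stop2("no valid split point")
  if (abs(renyi_order - 1) < 1e-12) {
    plogp <- ifelse(p > 0, p * log(p), 0)
    sb <- cumsum(plogp)
    sa <- sum(plogp) - sb
    hb <- -sb[valid] / pb[valid] + log(pb[valid])
    ha <- -sa[valid] / pa[valid] + log(pa[valid])
  } else {
    a <- renyi_order
    sb <- cumsum(p^a)
    sa <- sum(p^a) - sb
    hb <- (log(sb[valid]) - a * log(pb[valid])) / (1 - a)
    ha <- (log(sa[valid]) - a * log(pa[valid])) / (1 - a)
  }
  valid[which.max(hb + ha)] - 1L
}

#' Li minimum-cross-entropy threshold
#'
#' Minimizes Li's cross-entropy criterion
#' `eta(t) = -sum_{g<=t} g h(g) log mu_b(t) - sum_{g>t} g h(g) log mu_f(t)`
#' over every candidate level (the classical fixed-point iteration is only
#' a local optimizer of this criterion and can miss the global minimum on
#' multimodal histograms; the exhaustive scan over at most a few hundred
#' levels is exact and equally cheap).  Foreground is `level > t`.
#'
#' @param counts histogram counts for levels `0 .. length(counts) - 1`.
#' @return integer threshold level.
#' @export
li_threshold <- function(counts) {
  check_histogram(counts)
  g <- seq_along(counts) - 1
  wb <- cumsum(counts)
  wf <- sum(counts) - wb
  ab <- cumsum(g * counts)          # intensity mass below t
  af <- sum(g * counts) - ab
  valid <- which(wb > 0 & wf > 0)
  valid <- valid[valid < length(counts)]
  mb <- ab[valid] / wb[valid]
  mf <- af[valid] / wf[valid]
  eta <- -ab[valid] * ifelse(ab[valid] > 0, log(pmax(mb, 1e-300)), 0) -
    af[valid] * ifelse(af[valid] > 0, log(pmax(mf, 1e-300)), 0)
  as.integer(valid[which.min(eta)] - 1L)
}

## Histogram of a continuous-valued frame on n quantization levels over its
## own range (the 8-bit conversion implied by per-image auto-thresholding).
quantize_frame <- function(image, nlevels = 256L) {
  lo <- min(image); hi <- max(image)
  if (hi == lo) stop2("degenerate frame: constant intensity")
  q <- round_half_away((image - lo) / (hi - lo) * (nlevels - 1))
  list(levels = q, counts = tabulate(q + 1L, nbins = nlevels))
}

## Li threshold of one frame, returned as a logical foreground mask.
li_mask <- function(image, nlevels = 256L) {
  qf <- quantize_frame(image, nlevels)
  t <- li_threshold(qf$counts)
  qf$levels > t
}

#' Build the foreground mask of a frame pair
#'
#' Per-modality Li thresholds combined with a logical OR: a pixel is
#' foreground if it is foreground in either the SHG or the TPEF channel.
#'
#' @param shg_frame,tpef_frame co-registered numeric matrices.
#' @return logical matrix (TRUE = foreground) with attribute `method`.
#' @export
build_foreground_mask <- function(shg_frame, tpef_frame) {
  if (!identical(dim(shg_frame), dim(tpef_frame)))
    stop2("frames are not co-registered (shape mismatch)")
  m <- li_mask(shg_frame) | li_mask(tpef_frame)
  attr(m, "method") <- "Li-OR"
  m
}

#' Bin an image by block averaging
#'
#' Each output pixel is the arithmetic mean of its `factor x factor` input
#' block, so total intensity is conserved up to the `factor^2` scale.
#'
#' @param image numeric matrix with dimensions divisible by `factor`.
#' @param factor integer bin size (e.g. 4 for 512 -> 128).
#' @return binned matrix.
#' @export
bin_image <- function(image, factor = 4L) {
  d <- dim(image)
  if (any(d %% factor != 0))
    stop2("image dimensions must be divisible by the binning factor")
  nr <- d[1] %/% factor
  nc <- d[2] %/% factor
  ## average rows within blocks, then columns
  m <- matrix(colMeans(matrix(image, nrow = factor)), nrow = nr)
  t(matrix(colMeans(matrix(t(m), nrow = factor)), nrow = nc))
}

#' Renormalize a frame by its background mean
#'
#' Divides the frame by the mean intensity over the mask complement so
#' that the background mean of the output is 1.  Scale-invariant and
#' idempotent.
#'
#' @param image numeric matrix.
#' @param mask logical foreground mask of the same shape.
#' @return renormalized matrix.
#' @export
background_renormalize <- function(image, mask) {
  bg <- !mask
  if (!any(bg)) stop2("unusable frame: empty background")
  mu <- mean(image[bg])
  if (mu <= 0) stop2("unusable frame: nonpositive background mean")
  image / mu
}

## Pooled integer histogram over a list of integer-valued frames.
pooled_hist <- function(frames, nlevels) {
  counts <- integer(nlevels)
  for (m in frames) counts <- counts + tabulate(m + 1L, nbins = nlevels)
  counts
}

#' Segment collagen in an SHG stack
#'
#' The collagen path: each frame is Frangi-enhanced, the enhanced stack is
#' linearly rescaled to 16 bits over the entire stack, a single maximum
#' Renyi entropy threshold is computed from the pooled stack histogram and
#' applied to every frame.
#'
#' @param shg_frames list of SHG matrices (one ROI stack).
#' @param scales_px,beta,c_mode,scale_is_diameter passed to
#'   [frangi_vesselness()]; the automatic structure-norm constant `c` is
#'   shared across the whole stack (a frame of pure noise must not
#'   self-normalize its own noise to full response).
#' @param renyi_order passed to [max_entropy_threshold()].
#' @return list with `binary` (list of 0/1 matrices), `enhanced` (list of
#'   rescaled Frangi frames) and `threshold`.
#' @export
segment_collagen_pipeline <- function(shg_frames, scales_px = c(1.8, 4.9, 8),
                                      beta = 0.5, c_mode = "auto",
                                      scale_is_diameter = FALSE,
                                      renyi_order = 1) {
  if (identical(c_mode, "auto")) {
    ## stack-level c: half the maximum structure norm over all frames
    smax <- 0
    for (m in shg_frames) {
      ps <- frangi_core(m, scales_px, beta, scale_is_diameter)
      smax <- max(smax, vapply(ps, function(p) max(p$s), 0))
    }
    c_mode <- smax / 2
  }
  enhanced <- lapply(shg_frames, frangi_vesselness, scales_px = scales_px,
                     beta = beta, c_mode = c_mode,
                     scale_is_diameter = scale_is_diameter)
  scaled <- rescale_stack(enhanced, 16L)
  t <- max_entropy_threshold(pooled_hist(scaled, 65536L), renyi_order)
  list(binary = lapply(scaled, function(m) (m > t) * 1),
       enhanced = scaled, threshold = t)
}

#' Segment myocardium in a TPEF stack
#'
#' The TPEF path needs no enhancement: the stack is rescaled to 8 bits over
#' the entire stack and thresholded with a single stack-level maximum Renyi
#' entropy threshold.
#'
#' @param tpef_frames list of TPEF matrices (one ROI stack).
#' @param renyi_order passed to [max_entropy_threshold()].
#' @return list with `binary`, `scaled` and `threshold`.
#' @export
segment_tpef_pipeline <- function(tpef_frames, renyi_order = 1) {
  scaled <- rescale_stack(tpef_frames, 8L)
  t <- max_entropy_threshold(pooled_hist(scaled, 256L), renyi_order)
  list(binary = lapply(scaled, function(m) (m > t) * 1),
       scaled = scaled, threshold = t)
}
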