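## Synthetic two-channel fibrous-tissue image generator.
##
## Downstream stages (segmentation, fiber tracing, directionality, radiomics,
## classification) are exercised on images rendered from known ground truth:
## each frame is a pair of co-registered rasters, an SHG channel holding
## collagen fibers and a TPEF channel holding myocardium, both rendered as
## additive Gaussian-profile ridges plus background, shot noise and read
## noise.

#' Evaluate an expression under a fixed RNG seed
#'
#' Saves and restores the caller's RNG state so that seeded generation does
#' not perturb unrelated randomness.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @keywords internal
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Define a tissue phenotype for the synthetic generator
#'
#' A phenotype parameterizes one of the three histological classes seen in
#' infarcted myocardium: healthy `muscle` (TPEF-dominant, long parallel
#' myocyte fibers, sparse thin collagen), `border` (interlaced, longer and
#' thicker collagen among disordered myocardium) and `fibrosis` (SHG-dominant
#' mesh of thick wavy collagen with sparse amorphous TPEF signal).
#'
#' Orientation concentration `kappa` acts on doubled angles (axial data), so
#' `kappa = 0` is an isotropic fiber field and large `kappa` gives fibers
#' aligned with `collagen_orientation_mean_deg`.  `waviness` in `[0, 1]`
#' controls centerline curvature: 0 renders straight fibers with
#' straightness 1.
#'
#' @param label one of `"muscle"`, `"border"`, `"fibrosis"`.
#' @param collagen_fiber_count integer >= 0, collagen fibers per frame.
#' @param collagen_length_mean_um,collagen_length_sd_um fiber length
#'   distribution (um), truncated at > 0.
#' @param collagen_width_mean_um,collagen_width_sd_um fiber width
#'   distribution (um), truncated at > 0.
#' @param collagen_orientation_mean_deg mean axial orientation in `[0, 180)`.
#' @param collagen_orientation_kappa concentration (>= 0) on doubled angles.
#' @param collagen_waviness waviness in `[0, 1]`.
#' @param collagen_intensity_scale peak ridge intensity of collagen fibers
#'   (16-bit counts).
#' @param myocardium_fiber_count,myocardium_orientation_kappa,myocardium_intensity_scale
#'   TPEF-channel analogues.
#' @param myocardium_length_mean_um,myocardium_length_sd_um,myocardium_width_mean_um,myocardium_width_sd_um,myocardium_waviness
#'   myocyte fiber geometry; defaults give long, thick myofiber bundles.
#' @param background_level additive background (counts), both channels.
#' @param noise_gaussian_sd read-noise standard deviation (counts).
#' @return object of class `tissue_phenotype` (a validated list).
#' @export
tissue_phenotype <- function(label,
                             collagen_fiber_count,
                             collagen_length_mean_um, collagen_length_sd_um,
                             collagen_width_mean_um, collagen_width_sd_um,
                             collagen_orientation_mean_deg = 0,
                             collagen_orientation_kappa = 0,
                             collagen_waviness = 0,
                             collagen_intensity_scale = 400,
                             myocardium_fiber_count = 0,
                             myocardium_orientation_kappa = 0,
                             myocardium_intensity_scale = 400,
                             myocardium_length_mean_um = 300,
                             myocardium_length_sd_um = 60,
                             myocardium_width_mean_um = 12,
                             myocardium_width_sd_um = 2,
                             myocardium_waviness = 0.1,
                             background_level = 30,
                             noise_gaussian_sd = 6) {
  label <- match.arg(label, c("muscle", "border", "fibrosis"))
  p <- list(
    label = label,
    collagen_fiber_count = as.integer(collagen_fiber_count),
    collagen_length_mean_um = collagen_length_mean_um,
    collagen_length_sd_um = collagen_length_sd_um,
    collagen_width_mean_um = collagen_width_mean_um,
    collagen_width_sd_um = collagen_width_sd_um,
    collagen_orientation_mean_deg = collagen_orientation_mean_deg %% 180,
    collagen_orientation_kappa = collagen_orientation_kappa,
    collagen_waviness = collagen_waviness,
    collagen_intensity_scale = collagen_intensity_scale,
    myocardium_fiber_count = as.integer(myocardium_fiber_count),
    myocardium_orientation_kappa = myocardium_orientation_kappa,
    myocardium_intensity_scale = myocardium_intensity_scale,
    myocardium_length_mean_um = myocardium_length_mean_um,
    myocardium_length_sd_um = myocardium_length_sd_um,
    myocardium_width_mean_um = myocardium_width_mean_um,
    myocardium_width_sd_um = myocardium_width_sd_um,
    myocardium_waviness = myocardium_waviness,
    background_level = background_level,
    noise_gaussian_sd = noise_gaussian_sd
  )
  counts <- c(p$collagen_fiber_count, p$myocardium_fiber_count)
  if (any(counts < 0)) stop2("fiber counts must be >= 0")
  if (p$collagen_orientation_kappa < 0 || p$myocardium_orientation_kappa < 0)
    stop2("kappa must be >= 0")
  if (p$collagen_waviness < 0 || p$collagen_waviness > 1)
    stop2("waviness must lie in [0, 1]")
  pos <- c(p$collagen_length_mean_um, p$collagen_length_sd_um,
           p$collagen_width_mean_um, p$collagen_width_sd_um)
  if (any(pos <= 0)) stop2("length/width distribution parameters must be > 0")
  if (p$background_level < 0 || p$noise_gaussian_sd < 0)
    stop2("background and noise levels must be >= 0")
  if (p$background_level + p$collagen_intensity_scale > 65535 ||
      p$background_level + p$myocardium_intensity_scale > 65535)
    stop2("intensity scales exceed the 16-bit container")
  structure(p, class = "tissue_phenotype")
}

#' Default phenotype presets for the three tissue classes
#'
#' Presets encode the ordinal contrasts between healthy muscle, infarct
#' border and mature fibrosis: collagen intensity ratio near 0.1 for muscle
#' and near 0.3 for the pathological classes, more numerous / longer /
#' thicker collagen in the border, and a dense wavy collagen mesh with
#' sparse amorphous TPEF in fibrosis.  Counts are calibrated for the default
#' 512 px frame and are scaled by area when rendering at other sizes.
#'
#' @return named list of three `tissue_phenotype` objects.
#' @export
phenotype_presets <- function() {
  list(
    muscle = tissue_phenotype(
      "muscle",
      collagen_fiber_count = 14,
      collagen_length_mean_um = 22, collagen_length_sd_um = 9,
      collagen_width_mean_um = 3.5, collagen_width_sd_um = 0.4,
      collagen_orientation_mean_deg = 30, collagen_orientation_kappa = 8,
      collagen_waviness = 0.1, collagen_intensity_scale = 320,
      myocardium_fiber_count = 55, myocardium_orientation_kappa = 8,
      myocardium_intensity_scale = 500,
      myocardium_length_mean_um = 320, myocardium_length_sd_um = 60,
      myocardium_width_mean_um = 13, myocardium_width_sd_um = 2,
      myocardium_waviness = 0.08
    ),
    border = tissue_phenotype(
      "border",
      collagen_fiber_count = 50,
      collagen_length_mean_um = 31, collagen_length_sd_um = 9,
      collagen_width_mean_um = 3.9, collagen_width_sd_um = 0.3,
      collagen_orientation_mean_deg = 60, collagen_orientation_kappa = 1.2,
      collagen_waviness = 0.35, collagen_intensity_scale = 520,
      myocardium_fiber_count = 45, myocardium_orientation_kappa = 1.2,
      myocardium_intensity_scale = 480,
      myocardium_length_mean_um = 190, myocardium_length_sd_um = 50,
      myocardium_width_mean_um = 11, myocardium_width_sd_um = 2,
      myocardium_waviness = 0.3
    ),
    fibrosis = tissue_phenotype(
      "fibrosis",
      collagen_fiber_count = 80,
      collagen_length_mean_um = 26, collagen_length_sd_um = 7.5,
      collagen_width_mean_um = 4.1, collagen_width_sd_um = 0.3,
      collagen_orientation_mean_deg = 120, collagen_orientation_kappa = 2.5,
      collagen_waviness = 0.55, collagen_intensity_scale = 600,
      myocardium_fiber_count = 30, myocardium_orientation_kappa = 0.5,
      myocardium_intensity_scale = 350,
      myocardium_length_mean_um = 55, myocardium_length_sd_um = 15,
      myocardium_width_mean_um = 22, myocardium_width_sd_um = 4,
      myocardium_waviness = 0.4
    )
  )
}

#' Sample axial orientations from a doubled-angle von Mises model
#'
#' Fiber orientation is axial (theta and theta + 180 degrees are the same
#' fiber), so directions are drawn on the doubled circle with concentration
#' `kappa` around `2 * mean` and halved back into `[0, 180)`.  `kappa = 0`
#' gives the uniform axial distribution.  Sampling uses the Best-Fisher
#' rejection algorithm.
#'
#' @param n number of draws.
#' @param mean_deg axial mean in degrees.
#' @param kappa concentration >= 0.
#' @return orientations in degrees in `[0, 180)`.
#' @export
sample_axial_orientation <- function(n, mean_deg, kappa) {
  if (kappa < 0) stop2("kappa must be >= 0")
  if (kappa == 0) return(stats::runif(n, 0, 180))
  mu <- 2 * mean_deg * pi / 180
  ## Best & Fisher (1979) wrapped-Cauchy envelope rejection sampler.
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- stats::runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      phi <- mu + sign(u[3] - 0.5) * acos(f)
      out[i] <- phi
      i <- i + 1L
    }
  }
  ((out / 2) * 180 / pi) %% 180
}

## Build a wavy centerline of arc length len_px with initial heading
## angle_deg; heading oscillates sinusoidally with amplitude proportional to
## waviness so that straightness (chord / arc) decreases as waviness grows.
make_centerline <- function(len_px, angle_deg, waviness, step = 1) {
  n <- max(2L, ceiling(len_px / step) + 1L)
  s <- seq(0, len_px, length.out = n)
  theta0 <- angle_deg * pi / 180
  if (waviness > 0) {
    amp <- waviness * pi / 2
    phase <- stats::runif(1, 0, 2 * pi)
    theta <- theta0 + amp * sin(2 * pi * s / len_px + phase)
  } else {
    theta <- rep(theta0, n)
  }
  ds <- diff(s)
  ## headings at segment midpoints keep arc length exact
  mid <- (theta[-1] + theta[-n]) / 2
  x <- c(0, cumsum(ds * cos(mid)))
  y <- c(0, cumsum(ds * sin(mid)))
  cbind(x = x, y = y)
}

#' Sample one fiber from a phenotype
#'
#' Draws length and width from the phenotype's truncated normal
#' distributions, orientation from the doubled-angle axial model and builds
#' a (possibly wavy) centerline placed uniformly at random on the canvas.
#'
#' @param phenotype a [tissue_phenotype()].
#' @param channel `"SHG"` (collagen) or `"TPEF"` (myocardium).
#' @param size_px canvas side in pixels.
#' @param pixel_size_um pixel pitch in micrometers.
#' @return a `fiber_record`: list with `centerline` (n x 2 matrix, px),
#'   `length_um`, `width_um`, `width_px`, `straightness`, `angle_deg`.
#' @export
sample_fiber <- function(phenotype, channel = c("SHG", "TPEF"),
                         size_px = 512, pixel_size_um = 508 / 512) {
  channel <- match.arg(channel)
  p <- phenotype
  if (channel == "SHG") {
    lm <- p$collagen_length_mean_um; ls <- p$collagen_length_sd_um
    wm <- p$collagen_width_mean_um;  ws <- p$collagen_width_sd_um
    mu <- p$collagen_orientation_mean_deg
    kap <- p$collagen_orientation_kappa
    wav <- p$collagen_waviness
  } else {
    lm <- p$myocardium_length_mean_um; ls <- p$myocardium_length_sd_um
    wm <- p$myocardium_width_mean_um;  ws <- p$myocardium_width_sd_um
    mu <- p$collagen_orientation_mean_deg
    kap <- p$myocardium_orientation_kappa
    wav <- p$myocardium_waviness
  }
  rtpos <- function(mean, sd, floor_val = 1e-3) {
    for (i in 1:100) {
      v <- stats::rnorm(1, mean, sd)
      if (v > floor_val) return(v)
    }
    max(mean, floor_val)
  }
  length_um <- rtpos(lm, ls, 2 * pixel_size_um)
  width_um <- rtpos(wm, ws, pixel_size_um)
  angle <- sample_axial_orientation(1, mu, kap)
  len_px <- length_um / pixel_size_um
  cl <- make_centerline(len_px, angle, wav)
  ## place centroid uniformly, then clamp into the canvas
  cl[, 1] <- cl[, 1] - mean(cl[, 1]) + stats::runif(1, 1, size_px)
  cl[, 2] <- cl[, 2] - mean(cl[, 2]) + stats::runif(1, 1, size_px)
  cl[, 1] <- pmin(pmax(cl[, 1], 1), size_px)
  cl[, 2] <- pmin(pmax(cl[, 2], 1), size_px)
  arc <- sum(sqrt(rowSums(diff(cl)^2)))
  chord <- sqrt(sum((cl[nrow(cl), ] - cl[1, ])^2))
  straight <- if (arc > 0) min(chord / arc, 1) else 1
  structure(list(
    centerline = cl,
    length_um = arc * pixel_size_um,
    width_um = width_um,
    width_px = width_um / pixel_size_um,
    straightness = straight,
    angle_deg = (atan2(cl[nrow(cl), 2] - cl[1, 2],
                       cl[nrow(cl), 1] - cl[1, 1]) * 180 / pi) %% 180
  ), class = "fiber_record")
}

#' Render a fiber as an additive Gaussian ridge
#'
#' Adds to `canvas` a ridge whose cross-section is Gaussian with full width
#' at half maximum equal to `width_px` and whose intensity is maximal along
#' the centerline.  Rendering is additive: rendering two fibers sequentially
#' equals the sum of the individually rendered canvases.
#'
#' @param centerline n x 2 matrix of (x, y) positions in pixels (1-based,
#'   within the canvas).
#' @param width_px ridge FWHM in pixels, >= 1.
#' @param peak_intensity peak intensity added on the centerline.
#' @param canvas numeric matrix (rows = y, columns = x).
#' @return the canvas with the ridge added.
#' @export
render_fiber <- function(centerline, width_px, peak_intensity, canvas) {
  if (is.null(centerline) || NROW(centerline) == 0)
    stop2("empty centerline: nothing to render")
  if (width_px < 1) stop2("width_px must be >= 1")
  if (peak_intensity == 0) return(canvas)
  sigma <- width_px / (2 * sqrt(2 * log(2)))
  ## densify the polyline so point distance approximates curve distance
  cl <- centerline
  if (nrow(cl) > 1) {
    seg <- sqrt(rowSums(diff(cl)^2))
    keep <- seg > 0
    pts <- list(cl[1, , drop = FALSE])
    for (i in seq_along(seg)) {
      if (!keep[i]) next
      k <- max(1L, ceiling(seg[i] / 0.75))
      tt <- seq_len(k) / k
      pts[[length(pts) + 1L]] <-
        cbind(cl[i, 1] + tt * (cl[i + 1, 1] - cl[i, 1]),
              cl[i, 2] + tt * (cl[i + 1, 2] - cl[i, 2]))
    }
    q <- do.call(rbind, pts)
  } else q <- cl
  pad <- ceiling(3.5 * sigma)
  nx <- ncol(canvas); ny <- nrow(canvas)
  x0 <- max(1L, floor(min(q[, 1])) - pad); x1 <- min(nx, ceiling(max(q[, 1])) + pad)
  y0 <- max(1L, floor(min(q[, 2])) - pad); y1 <- min(ny, ceiling(max(q[, 2])) + pad)
  xs <- x0:x1; ys <- y0:y1
  ## min squared distance to the densified centerline, accumulated by
  ## stamping a local window around each sample point
  block <- matrix(Inf, length(ys), length(xs))
  for (p in seq_len(nrow(q))) {
    wx0 <- max(x0, floor(q[p, 1]) - pad); wx1 <- min(x1, ceiling(q[p, 1]) + pad)
    wy0 <- max(y0, floor(q[p, 2]) - pad); wy1 <- min(y1, ceiling(q[p, 2]) + pad)
    jj <- (wx0:wx1) - x0 + 1L
    ii <- (wy0:wy1) - y0 + 1L
    d2 <- outer((wy0:wy1) - q[p, 2], (wx0:wx1) - q[p, 1],
                function(a, b) a^2 + b^2)
    block[ii, jj] <- pmin(block[ii, jj], d2)
  }
  canvas[ys, xs] <- canvas[ys, xs] + peak_intensity * exp(-block / (2 * sigma^2))
  canvas
}

#' Generate one two-channel frame with ground truth
#'
#' Renders the phenotype's collagen fibers into the SHG channel and
#' myocardium fibers into the TPEF channel, adds background, Poisson shot
#' noise and Gaussian read noise, and clips to the 16-bit container.  The
#' output is deterministic given `seed`.
#'
#' @param phenotype a [tissue_phenotype()].
#' @param size_px frame side in pixels (>= 64; default 512, the acquisition
#'   geometry of a 508 um field of view).
#' @param pixel_size_um pixel pitch in micrometers.
#' @param seed integer seed.
#' @return list with `shg` and `tpef` integer matrices, `pixel_size_um`,
#'   `bit_depth = 16` and `ground_truth` (per-channel fiber records, the
#'   phenotype and the seed).
#' @export
generate_image <- function(phenotype, size_px = 512,
                           pixel_size_um = 508 / 512, seed = 1) {
  if (size_px < 64) stop2("size_px must be >= 64")
  with_seed(seed, {
    area_scale <- (size_px / 512)^2
    n_col <- round(phenotype$collagen_fiber_count * area_scale)
    n_myo <- round(phenotype$myocardium_fiber_count * area_scale)
    shg <- matrix(0, size_px, size_px)
    tpef <- matrix(0, size_px, size_px)
    fib_shg <- vector("list", n_col)
    fib_tpef <- vector("list", n_myo)
    for (i in seq_len(n_col)) {
      f <- sample_fiber(phenotype, "SHG", size_px, pixel_size_um)
      f$peak <- phenotype$collagen_intensity_scale * stats::rlnorm(1, 0, 0.2)
      fib_shg[[i]] <- f
      shg <- render_fiber(f$centerline, max(1, f$width_px), f$peak, shg)
    }
    for (i in seq_len(n_myo)) {
      f <- sample_fiber(phenotype, "TPEF", size_px, pixel_size_um)
      f$peak <- phenotype$myocardium_intensity_scale * stats::rlnorm(1, 0, 0.2)
      fib_tpef[[i]] <- f
      tpef <- render_fiber(f$centerline, max(1, f$width_px), f$peak, tpef)
    }
    add_noise <- function(clean) {
      lam <- clean + phenotype$background_level
      out <- stats::rpois(length(lam), lam) +
        stats::rnorm(length(lam), 0, phenotype$noise_gaussian_sd)
      m <- matrix(round_half_away(out), nrow(clean), ncol(clean))
      ## 16-bit container, ~10-bit signal range (detector saturation)
      pmin(pmax(m, 0), 1023)
    }
    list(
      shg = add_noise(shg),
      tpef = add_noise(tpef),
      pixel_size_um = pixel_size_um,
      bit_depth = 16L,
      ground_truth = list(shg_fibers = fib_shg, tpef_fibers = fib_tpef,
                          phenotype = phenotype, seed = seed)
    )
  })
}

## Apply multiplicative / angular jitter to a phenotype (per-ROI batch
## structure).  sd = 0 returns the phenotype unchanged.
jitter_phenotype <- function(phenotype, sd, seed) {
  if (sd == 0) return(phenotype)
  with_seed(seed, {
    p <- unclass(phenotype)
    mult <- function(v) v * stats::rlnorm(1, 0, sd)
    for (f in c("collagen_fiber_count", "collagen_length_mean_um",
                "collagen_width_mean_um", "collagen_intensity_scale",
                "myocardium_fiber_count", "myocardium_intensity_scale",
                "collagen_orientation_kappa", "myocardium_orientation_kappa"))
      p[[f]] <- mult(p[[f]])
    p$collagen_fiber_count <- max(0L, as.integer(round(p$collagen_fiber_count)))
    p$myocardium_fiber_count <- max(0L, as.integer(round(p$myocardium_fiber_count)))
    p$collagen_orientation_mean_deg <-
      (p$collagen_orientation_mean_deg + stats::rnorm(1, 0, 60 * sd)) %% 180
    structure(p, class = "tissue_phenotype")
  })
}

#' Generate a labeled dataset of two-channel frames
#'
#' Mirrors the study layout: each class is imaged at several regions of
#' interest (ROIs), each ROI contributing a depth stack of frames.  ROI-level
#' parameter jitter creates within-class batch structure, and ROIs are
#' partitioned into two pseudo-subjects (odd / even ROI index) so that
#' train/test splits can be segregated by subject.
#'
#' @param presets named list of `tissue_phenotype` (default
#'   [phenotype_presets()]).
#' @param n_per_class_per_roi frames per ROI (>= 1).
#' @param n_rois ROIs per class.
#' @param seed integer seed.
#' @param size_px frame side in pixels.
#' @param pixel_size_um pixel pitch.
#' @param roi_jitter_sd lognormal sd of the per-ROI parameter jitter
#'   (0 disables jitter).
#' @return list with `frames` (list of [generate_image()] outputs) and
#'   `manifest` (data frame: frame, class, roi, subject, seed and the
#'   jittered phenotype parameters).
#' @export
generate_dataset <- function(presets = phenotype_presets(),
                             n_per_class_per_roi = 10, n_rois = 2,
                             seed = 1, size_px = 512,
                             pixel_size_um = 508 / 512,
                             roi_jitter_sd = 0.12) {
  if (n_per_class_per_roi < 1) stop2("n_per_class_per_roi must be >= 1")
  frames <- list()
  rows <- list()
  k <- 0L
  for (ci in seq_along(presets)) {
    cls <- names(presets)[ci]
    for (ri in seq_len(n_rois)) {
      roi_id <- sprintf("%s_roi%d", cls, ri)
      subject <- if (ri %% 2 == 1) "subject1" else "subject2"
      pj <- jitter_phenotype(presets[[ci]], roi_jitter_sd,
                             derive_seed(seed, ci * 1000 + ri))
      for (fi in seq_len(n_per_class_per_roi)) {
        k <- k + 1L
        fseed <- derive_seed(seed, ci * 100000 + ri * 1000 + fi)
        frames[[k]] <- generate_image(pj, size_px, pixel_size_um, fseed)
        rows[[k]] <- data.frame(
          frame = k, class = cls, roi = roi_id, subject = subject,
          seed = fseed,
          collagen_fiber_count = pj$collagen_fiber_count,
          collagen_length_mean_um = pj$collagen_length_mean_um,
          collagen_width_mean_um = pj$collagen_width_mean_um,
          collagen_orientation_mean_deg = pj$collagen_orientation_mean_deg,
          collagen_orientation_kappa = pj$collagen_orientation_kappa,
          collagen_waviness = pj$collagen_waviness,
          myocardium_fiber_count = pj$myocardium_fiber_count,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  list(frames = frames, manifest = do.call(rbind, rows))
}
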