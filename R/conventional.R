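## The 16 conventional imaging features: collagen amount, skeleton-based
## fiber morphology, and Fourier-spectrum directionality with circular
## statistics.

#' Collagen intensity ratio
#'
#' `C_I = mean(SHG) / (mean(SHG) + mean(TPEF))` with means over the full
#' frame; the fraction of total signal contributed by the collagen channel.
#'
#' @param shg_frame,tpef_frame co-registered numeric matrices.
#' @return value in `[0, 1]`.
#' @export
collagen_intensity_ratio <- function(shg_frame, tpef_frame) {
  if (!identical(dim(shg_frame), dim(tpef_frame)))
    stop2("frames are not co-registered")
  ms <- mean(shg_frame); mt <- mean(tpef_frame)
  if (ms + mt == 0) stop2("undefined ratio: both channels are all zero")
  ms / (ms + mt)
}

#' Collagen segmentation ratio
#'
#' `C_S = N_SHG / (N_SHG + N_TPEF)` where `N` counts segmented foreground
#' pixels in each channel's binary mask.
#'
#' @param shg_mask,tpef_mask binary matrices of the same shape.
#' @return value in `[0, 1]`.
#' @export
collagen_segmentation_ratio <- function(shg_mask, tpef_mask) {
  if (!identical(dim(shg_mask), dim(tpef_mask))) stop2("shape mismatch")
  ns <- sum(shg_mask != 0); nt <- sum(tpef_mask != 0)
  if (ns + nt == 0) stop2("undefined ratio: both masks are empty")
  ns / (ns + nt)
}

## value of the (r+dr, c+dc) neighbor at each pixel, zero outside
shift_mat <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(0, nr, nc)
  rs <- max(1, 1 + dr):min(nr, nr + dr)
  cs <- max(1, 1 + dc):min(nc, nc + dc)
  out[rs - dr, cs - dc] <- m[rs, cs]
  out
}

#' Skeletonize a binary image (Zhang-Suen thinning)
#'
#' Iterative morphological thinning to a one-pixel-wide, 8-connected
#' skeleton.
#'
#' @param binary 0/1 matrix.
#' @return 0/1 matrix of the skeleton.
#' @export
skeletonize <- function(binary) {
  b <- (binary != 0) * 1
  repeat {
    changed <- FALSE
    for (sub in 1:2) {
      p2 <- shift_mat(b, -1, 0); p3 <- shift_mat(b, -1, 1)
      p4 <- shift_mat(b, 0, 1);  p5 <- shift_mat(b, 1, 1)
      p6 <- shift_mat(b, 1, 0);  p7 <- shift_mat(b, 1, -1)
      p8 <- shift_mat(b, 0, -1); p9 <- shift_mat(b, -1, -1)
      bsum <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
      ## number of 0 -> 1 transitions around the ring
      a <- (p2 < p3) + (p3 < p4) + (p4 < p5) + (p5 < p6) +
        (p6 < p7) + (p7 < p8) + (p8 < p9) + (p9 < p2)
      if (sub == 1) {
        cond <- b == 1 & bsum >= 2 & bsum <= 6 & a == 1 &
          p2 * p4 * p6 == 0 & p4 * p6 * p8 == 0
      } else {
        cond <- b == 1 & bsum >= 2 & bsum <= 6 & a == 1 &
          p2 * p4 * p8 == 0 & p2 * p6 * p8 == 0
      }
      if (any(cond)) {
        b[cond] <- 0
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  b
}

## 8-connected labeling built on EBImage's 4-connected bwlabel by merging
## labels that touch diagonally.
label8 <- function(binary) {
  l <- EBImage::bwlabel(binary != 0)
  nl <- max(l)
  if (nl <= 1) return(l)
  parent <- seq_len(nl)
  findp <- function(i) {
    i <- as.integer(i)
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  for (d in list(c(-1, -1), c(-1, 1))) {
    nb <- shift_mat(l, d[1], d[2])
    sel <- l > 0 & nb > 0 & nb != l
    if (!any(sel)) next
    pairs <- unique(cbind(l[sel], nb[sel]))
    for (k in seq_len(nrow(pairs))) {
      a <- findp(pairs[k, 1]); b <- findp(pairs[k, 2])
      if (a != b) parent[b] <- a
    }
  }
  root <- vapply(seq_len(nl), findp, 1L)
  compact <- match(root, unique(root))
  out <- l
  out[l > 0] <- compact[l[l > 0]]
  out
}

## Order the pixels of a thin 8-connected branch into a path.  `idx` is a
## 2-column matrix of (row, col).  Greedy nearest-neighbor walk from an
## endpoint (or an arbitrary pixel for loops).
order_branch <- function(idx) {
  n <- nrow(idx)
  if (n <= 2) return(idx)
  key <- idx[, 1] * 1e6 + idx[, 2]
  nb_count <- integer(n)
  pos <- new.env(hash = TRUE)
  for (i in seq_len(n)) assign(as.character(key[i]), i, envir = pos)
  neigh <- vector("list", n)
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  for (i in seq_len(n)) {
    ks <- (idx[i, 1] + offs$dr) * 1e6 + (idx[i, 2] + offs$dc)
    hit <- ks[vapply(as.character(ks), exists, TRUE, envir = pos,
                     inherits = FALSE)]
    neigh[[i]] <- vapply(as.character(hit), get, 1L, envir = pos,
                         inherits = FALSE)
    nb_count[i] <- length(neigh[[i]])
  }
  start <- which(nb_count <= 1)[1]
  if (is.na(start)) start <- 1L
  path <- integer(n)
  visited <- logical(n)
  cur <- start
  for (step in seq_len(n)) {
    path[step] <- cur
    visited[cur] <- TRUE
    nxt <- neigh[[cur]][!visited[neigh[[cur]]]]
    if (length(nxt) == 0) {
      path <- path[seq_len(step)]
      break
    }
    if (length(nxt) > 1) {
      ## prefer the closest (4-connected before diagonal)
      d <- (idx[nxt, 1] - idx[cur, 1])^2 + (idx[nxt, 2] - idx[cur, 2])^2
      nxt <- nxt[which.min(d)]
    } else nxt <- nxt[1]
    cur <- nxt
  }
  idx[path, , drop = FALSE]
}

## Distance-transform widths along a centerline.  With an enhanced frame,
## the mask is refined to the half-maximum footprint of the ridge around
## this fiber before taking distances.
fiber_widths <- function(binary_frame, enhanced_frame, ipts, dmap) {
  if (is.null(enhanced_frame)) return(dmap[ipts])
  r0 <- max(1, min(ipts[, 1]) - 20); r1 <- min(nrow(binary_frame), max(ipts[, 1]) + 20)
  c0 <- max(1, min(ipts[, 2]) - 20); c1 <- min(ncol(binary_frame), max(ipts[, 2]) + 20)
  half <- mean(enhanced_frame[ipts]) / 2
  sub <- binary_frame[r0:r1, c0:c1] != 0 & enhanced_frame[r0:r1, c0:c1] >= half
  dsub <- EBImage::distmap(sub)
  dsub[cbind(ipts[, 1] - r0 + 1L, ipts[, 2] - c0 + 1L)]
}

## unit direction of the last `k` points of a path, pointing towards its end
end_direction <- function(path, k = 5) {
  n <- nrow(path)
  a <- path[max(1, n - k), ]
  b <- path[n, ]
  v <- b - a
  nv <- sqrt(sum(v^2))
  if (nv == 0) c(1, 0) else v / nv
}

#' Trace fibers from a binary collagen mask
#'
#' A skeleton-based fiber extractor standing in for curvelet-based tools:
#' the foreground is thinned to a skeleton, the skeleton is split at
#' junction pixels, branches meeting at a junction are merged when they
#' continue within `merge_angle_deg` of a straight line, and fibers shorter
#' than `min_length_px` are pruned.  Per fiber: length is the centerline
#' arc length, width twice the mean distance-transform value along the
#' centerline (minus the one-pixel discretization offset), straightness the
#' endpoint distance over arc length, and the angle that of the
#' endpoint-to-endpoint chord in `[0, 180)`.
#'
#' @param binary_frame 0/1 collagen mask.
#' @param enhanced_frame optional ridge-enhanced intensity frame (same
#'   shape).  When given, fiber width is measured on the half-maximum
#'   footprint of the enhanced ridge around each centerline, which stays
#'   tight even when the stack-level entropy threshold is loose; without
#'   it the distance transform of `binary_frame` is used directly.
#' @param pixel_size_um pixel pitch in micrometers.
#' @param min_length_px prune fibers shorter than this (px).
#' @param merge_angle_deg maximal turn angle for merging collinear branches.
#' @return list of `fiber_record`s (possibly empty).
#' @export
trace_fibers <- function(binary_frame, enhanced_frame = NULL,
                         pixel_size_um = 508 / 512,
                         min_length_px = 15, merge_angle_deg = 30) {
  if (sum(binary_frame != 0) == 0) return(list())
  skel <- skeletonize(binary_frame)
  dmap <- EBImage::distmap(binary_frame != 0)
  ## crossing number: a pixel is a junction when >= 3 distinct skeleton
  ## paths leave it (robust on diagonal staircases, unlike a raw
  ## neighbor count)
  p2 <- shift_mat(skel, -1, 0); p3 <- shift_mat(skel, -1, 1)
  p4 <- shift_mat(skel, 0, 1);  p5 <- shift_mat(skel, 1, 1)
  p6 <- shift_mat(skel, 1, 0);  p7 <- shift_mat(skel, 1, -1)
  p8 <- shift_mat(skel, 0, -1); p9 <- shift_mat(skel, -1, -1)
  crossings <- (p2 < p3) + (p3 < p4) + (p4 < p5) + (p5 < p6) +
    (p6 < p7) + (p7 < p8) + (p8 < p9) + (p9 < p2)
  junction <- skel == 1 & crossings >= 3
  branch_px <- skel == 1 & !junction
  lab <- label8(branch_px)
  nbr <- max(lab)
  if (nbr == 0) return(list())
  paths <- vector("list", nbr)
  px <- which(lab > 0, arr.ind = TRUE)
  lv <- lab[lab > 0]
  for (i in seq_len(nbr)) {
    paths[[i]] <- order_branch(px[lv == i, , drop = FALSE])
  }
  ## merge branches across junction clusters when they continue straight
  parent <- seq_len(nbr)
  findp <- function(i) {
    i <- as.integer(i)
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  ## which branch ends touch which junction cluster
  jlab <- label8(junction)
  if (max(jlab) > 0) {
    ends <- list()  # each: branch id, which end (1 head / 2 tail), direction
    for (i in seq_len(nbr)) {
      p <- paths[[i]]
      for (e in 1:2) {
        pt <- if (e == 1) p[1, ] else p[nrow(p), ]
        dir <- if (e == 1) end_direction(p[rev(seq_len(min(nrow(p), 6))), ,
                                           drop = FALSE])
               else end_direction(p)
        ## junction cluster adjacent to this end, if any
        rr <- pt[1] + (-1:1); cc <- pt[2] + (-1:1)
        rr <- rr[rr >= 1 & rr <= nrow(jlab)]
        cc <- cc[cc >= 1 & cc <= ncol(jlab)]
        js <- unique(jlab[rr, cc])
        js <- js[js > 0]
        for (j in js)
          ends[[length(ends) + 1L]] <- list(branch = i, junction = j,
                                            dir = dir)
      }
    }
    if (length(ends) > 0) {
      jid <- vapply(ends, function(e) e$junction, 1)
      for (j in unique(jid)) {
        es <- ends[jid == j]
        if (length(es) < 2) next
        ## pair ends whose directions are most nearly opposite
        used <- logical(length(es))
        repeat {
          best <- NULL; best_ang <- merge_angle_deg
          for (u in seq_along(es)) for (v in seq_along(es)) {
            if (v <= u || used[u] || used[v]) next
            if (es[[u]]$branch == es[[v]]$branch) next
            cosang <- -sum(es[[u]]$dir * es[[v]]$dir)
            ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
            if (ang < best_ang) {
              best <- c(u, v); best_ang <- ang
            }
          }
          if (is.null(best)) break
          used[best] <- TRUE
          a <- findp(es[[best[1]]]$branch)
          b <- findp(es[[best[2]]]$branch)
          if (a != b) parent[b] <- a
        }
      }
    }
  }
  groups <- split(seq_len(nbr), vapply(seq_len(nbr), findp, 1L))
  fibers <- list()
  for (g in groups) {
    ## chain the group's branch paths by greedy end-matching
    pts <- paths[[g[1]]]
    remaining <- g[-1]
    while (length(remaining) > 0) {
      head_pt <- pts[1, ]; tail_pt <- pts[nrow(pts), ]
      bestd <- Inf; bestk <- NA; bestflip <- FALSE; besthead <- FALSE
      for (k in seq_along(remaining)) {
        q <- paths[[remaining[k]]]
        for (hd in c(TRUE, FALSE)) for (fl in c(FALSE, TRUE)) {
          anchor <- if (hd) head_pt else tail_pt
          qpt <- if (fl) q[nrow(q), ] else q[1, ]
          d <- sum((anchor - qpt)^2)
          if (d < bestd) {
            bestd <- d; bestk <- k; bestflip <- fl; besthead <- hd
          }
        }
      }
      q <- paths[[remaining[bestk]]]
      if (bestflip) q <- q[rev(seq_len(nrow(q))), , drop = FALSE]
      pts <- if (besthead) rbind(q[rev(seq_len(nrow(q))), , drop = FALSE], pts)
             else rbind(pts, q)
      remaining <- remaining[-bestk]
    }
    ## smooth the ordered centerline: staircase jitter of the raster
    ## skeleton otherwise inflates the arc length
    if (nrow(pts) >= 7) {
      sm <- apply(pts, 2, function(v) stats::filter(v, rep(1 / 5, 5)))
      keep <- !is.na(sm[, 1])
      pts <- rbind(pts[1, ], sm[keep, , drop = FALSE], pts[nrow(pts), ])
    }
    arc <- if (nrow(pts) > 1) sum(sqrt(rowSums(diff(pts)^2))) else 0
    if (arc < min_length_px) next
    chord <- sqrt(sum((pts[nrow(pts), ] - pts[1, ])^2))
    ipts <- cbind(pmin(pmax(round(pts[, 1]), 1), nrow(binary_frame)),
                  pmin(pmax(round(pts[, 2]), 1), ncol(binary_frame)))
    widths <- fiber_widths(binary_frame, enhanced_frame, ipts, dmap)
    fibers[[length(fibers) + 1L]] <- structure(list(
      centerline = cbind(x = pts[, 2], y = pts[, 1]),
      length_um = arc * pixel_size_um,
      width_um = max(2 * mean(widths) - 0.5, 1) * pixel_size_um,
      straightness = min(chord / arc, 1),
      angle_deg = (atan2(pts[nrow(pts), 1] - pts[1, 1],
                         pts[nrow(pts), 2] - pts[1, 2]) * 180 / pi) %% 180
    ), class = "fiber_record")
  }
  fibers
}

#' Summarize fiber morphology
#'
#' Count plus mean and population standard deviation of fiber length,
#' width and straightness; an empty fiber list yields a zero count and
#' missing values for the six moments.
#'
#' @param fibers list of `fiber_record`s.
#' @return named numeric vector of length 7.
#' @export
fiber_morphology_summary <- function(fibers) {
  if (length(fibers) == 0)
    return(c(fiber.count = 0, fiber.length.avg = NA, fiber.length.std = NA,
             fiber.width.avg = NA, fiber.width.std = NA,
             fiber.straightness.avg = NA, fiber.straightness.std = NA))
  len <- vapply(fibers, function(f) f$length_um, 1)
  wid <- vapply(fibers, function(f) f$width_um, 1)
  str <- vapply(fibers, function(f) f$straightness, 1)
  c(fiber.count = length(fibers),
    fiber.length.avg = mean(len), fiber.length.std = sd_pop(len),
    fiber.width.avg = mean(wid), fiber.width.std = sd_pop(wid),
    fiber.straightness.avg = mean(str), fiber.straightness.std = sd_pop(str))
}

#' Orientation histogram of an image by the Fourier-spectrum method
#'
#' The windowed power spectrum is binned by orientation: spectral energy at
#' spatial-frequency angle `phi` corresponds to image structures oriented
#' at `phi + 90` degrees.  Returns a normalized axial histogram over
#' `[0, 180)` with 1-degree bins.
#'
#' @param frame 2-D numeric matrix with nonzero variance.
#' @return object of class `orientation_histogram`: numeric vector of 180
#'   nonnegative frequencies summing to 1, with attribute `source`.
#' @export
directionality_histogram <- function(frame) {
  if (stats::var(as.vector(frame)) == 0)
    stop2("degenerate input: constant frame")
  nr <- nrow(frame); nc <- ncol(frame)
  wr <- 0.5 * (1 - cos(2 * pi * seq_len(nr) / (nr + 1)))
  wc <- 0.5 * (1 - cos(2 * pi * seq_len(nc) / (nc + 1)))
  f <- stats::fft((frame - mean(frame)) * outer(wr, wc))
  p <- Mod(f)^2
  fr <- c(0:(nr %/% 2), -((nr - nr %/% 2 - 1):1))[seq_len(nr)]
  fc <- c(0:(nc %/% 2), -((nc - nc %/% 2 - 1):1))[seq_len(nc)]
  v <- matrix(fr, nr, nc)        # y-frequency
  u <- matrix(fc, nr, nc, byrow = TRUE)  # x-frequency
  rho <- sqrt((u / nc)^2 + (v / nr)^2)
  sel <- rho > 1.5 / min(nr, nc) & rho <= 0.5
  theta <- (atan2(v[sel], u[sel]) * 180 / pi + 90) %% 180
  b <- floor(theta) + 1L
  h <- as.vector(rowsum(p[sel], b))
  out <- numeric(180)
  out[sort(unique(b))] <- h
  orientation_histogram(out / sum(out), source = "spectrum")
}

#' Construct an orientation histogram object
#'
#' @param f 180 nonnegative bin frequencies over `[0, 180)` (1-degree
#'   bins); normalized to sum 1.
#' @param source provenance tag (`"SHG"`, `"TPEF"`, `"fiber_angles"`, ...).
#' @return object of class `orientation_histogram`.
#' @export
orientation_histogram <- function(f, source = "unknown") {
  if (length(f) != 180 || any(f < 0)) stop2("f must be 180 nonnegative bins")
  s <- sum(f)
  if (s <= 0) stop2("empty histogram")
  structure(f / s, source = source, class = "orientation_histogram")
}

#' Orientation histogram of traced fiber angles
#'
#' @param fibers non-empty list of `fiber_record`s.
#' @return an [orientation_histogram()].
#' @export
fiber_angle_histogram <- function(fibers) {
  if (length(fibers) == 0) stop2("degenerate input: no fibers")
  ang <- vapply(fibers, function(f) f$angle_deg, 1) %% 180
  h <- tabulate(floor(ang) + 1L, nbins = 180)
  orientation_histogram(h / sum(h), source = "fiber_angles")
}

#' Circular statistics of an orientation histogram
#'
#' Computes the mean vector `(X, Y) = (sum f cos(theta), sum f sin(theta))`
#' over bin centers `theta` in radians (no angle doubling: the literal
#' first-moment form, under which a uniform axial histogram has MVL around
#' 0.64 rather than 0), the mean vector length `MVL = sqrt(X^2 + Y^2)`, the
#' mean angle as the atan2 of the mean vector mapped to `[0, pi)`, and the
#' range `R`: the length in radians of the shortest circularly contiguous
#' run of bins whose summed weight strictly exceeds one half (exhaustive
#' scan with wraparound; ties broken by the shorter arc, then the smaller
#' start angle).  A doubled-angle MVL (`mvl_axial`), the proper axial
#' concentration measure that is 0 for uniform data, is returned as a
#' separate diagnostic.
#'
#' @param h an [orientation_histogram()] or a normalized numeric vector of
#'   bin frequencies over `[0, pi)`.
#' @return list with `X`, `Y`, `mvl`, `theta_bar` (radians in `[0, pi)`),
#'   `range_rad`, `range_bins` and `mvl_axial`.
#' @export
circular_summary <- function(h) {
  f <- as.numeric(h)
  if (abs(sum(f) - 1) > 1e-9) stop2("histogram is not normalized")
  n <- length(f)
  theta <- (seq_len(n) - 1) * pi / n
  x <- sum(f * cos(theta))
  y <- sum(f * sin(theta))
  mvl <- sqrt(x^2 + y^2)
  theta_bar <- atan2(y, x) %% pi
  ## shortest wraparound run with weight strictly > 1/2
  cs <- cumsum(c(0, f, f))
  range_bins <- NA_integer_
  start_bin <- NA_integer_
  for (len in seq_len(n)) {
    w <- cs[(1:n) + len] - cs[1:n]
    ## strict "> 1/2" with a guard against floating-point ties
    hit <- which(w > 0.5 + 1e-12)
    if (length(hit) > 0) {
      range_bins <- len
      start_bin <- hit[1]
      break
    }
  }
  z <- complex(modulus = f, argument = 2 * theta)
  list(X = x, Y = y, mvl = mvl, theta_bar = theta_bar,
       range_rad = range_bins * pi / n, range_bins = range_bins,
       start_bin = start_bin, mvl_axial = Mod(sum(z)))
}

#' Axial mismatch between two mean angles
#'
#' Circular distance between the mean angles of two orientation summaries
#' with period pi, giving a value in `[0, pi/2]`.
#'
#' @param summary_shg,summary_tpef outputs of [circular_summary()].
#' @return mismatch in radians.
#' @export
angle_mismatch <- function(summary_shg, summary_tpef) {
  d <- abs(summary_shg$theta_bar - summary_tpef$theta_bar) %% pi
  min(d, pi - d)
}

#' Assemble the 16 conventional features of one frame
#'
#' @param shg_frame,tpef_frame raw co-registered channel matrices.
#' @param shg_mask,tpef_mask binary segmentation masks from the
#'   collagen/TPEF pipelines.
#' @param fibers traced fibers of the frame ([trace_fibers()]).
#' @return named numeric vector of length 16; missing-value markers
#'   propagate where a quantity is undefined (e.g. no fibers traced).
#' @export
conventional_feature_vector <- function(shg_frame, tpef_frame,
                                        shg_mask, tpef_mask, fibers) {
  ci <- collagen_intensity_ratio(shg_frame, tpef_frame)
  cs <- tryCatch(collagen_segmentation_ratio(shg_mask, tpef_mask),
                 error = function(e) NA_real_)
  morph <- fiber_morphology_summary(fibers)
  if (length(fibers) > 0) {
    cf <- circular_summary(fiber_angle_histogram(fibers))
    ctfire_mvl <- cf$mvl; ctfire_range <- cf$range_rad
  } else {
    ctfire_mvl <- NA_real_; ctfire_range <- NA_real_
  }
  s_shg <- tryCatch(circular_summary(directionality_histogram(shg_frame)),
                    error = function(e) NULL)
  s_tpef <- tryCatch(circular_summary(directionality_histogram(tpef_frame)),
                     error = function(e) NULL)
  mm <- if (!is.null(s_shg) && !is.null(s_tpef))
    angle_mismatch(s_shg, s_tpef) else NA_real_
  c(collagen.intensity = ci,
    collagen.segmentation = cs,
    morph,
    ctfire.mvl = ctfire_mvl,
    ctfire.range = ctfire_range,
    shg.mvl = if (is.null(s_shg)) NA_real_ else s_shg$mvl,
    shg.range = if (is.null(s_shg)) NA_real_ else s_shg$range_rad,
    tpef.mvl = if (is.null(s_tpef)) NA_real_ else s_tpef$mvl,
    tpef.range = if (is.null(s_tpef)) NA_real_ else s_tpef$range_rad,
    shg.tpef.mismatch = mm)
}

#' Names of the 16 conventional features
#' @return character vector of length 16 in canonical order.
#' @export
conventional_feature_names <- function() {
  c("collagen.intensity", "collagen.segmentation", "fiber.count",
    "fiber.length.avg", "fiber.length.std", "fiber.width.avg",
    "fiber.width.std", "fiber.straightness.avg", "fiber.straightness.std",
    "ctfire.mvl", "ctfire.range", "shg.mvl", "shg.range",
    "tpef.mvl", "tpef.range", "shg.tpef.mismatch")
}
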