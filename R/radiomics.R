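## 2-D IBSI-style radiomic feature panel on masked, binned, renormalized
## 8-bit images: intensity statistics, intensity histogram,
## intensity-volume histogram, local intensity, 2-D morphology, and the
## GLCM / GLRLM / GLSZM / NGTDM / NGLDM texture families.
##
## Conventions (documented once, used by every family):
##  * gray values enter texture formulas 1-based (g = intensity + 1,
##    levels 1..256) so low-gray-level emphases are finite at intensity 0;
##  * Ng = 256, the full discretization, in normalized inverse-difference
##    weights;
##  * directional families (GLCM, GLRLM) compute features per direction
##    over the 4 axial/diagonal 2-D directions and average them
##    ("2D, averaged" aggregation);
##  * undefined features (degenerate single-level regions, empty
##    denominators) are returned as NA, never silently zeroed.

RAD_NG <- 256L

#' Construct a discretized image for radiomics
#'
#' @param img integer matrix with levels in `0 .. 255`.
#' @param mask logical (or 0/1) foreground mask, same shape, non-empty.
#' @param modality tag (`"SHG"` or `"TPEF"`).
#' @return object of class `discretized_image`.
#' @export
discretized_image <- function(img, mask, modality = "SHG") {
  mask <- mask != 0
  if (!identical(dim(img), dim(mask))) stop2("img/mask shape mismatch")
  if (!any(mask)) stop2("mask is empty")
  if (any(img < 0 | img > 255 | img != floor(img)))
    stop2("img must hold integer levels in 0..255")
  structure(list(img = img, mask = mask, modality = modality),
            class = "discretized_image")
}

#' Preprocess a dataset of frame pairs for radiomics
#'
#' Mirrors the acquisition-to-features conditioning: each 512 px channel is
#' binned 4x4 by averaging to 128 px, a Li OR foreground mask is built at
#' the binned resolution, each modality is divided by its background mean,
#' and finally each modality is linearly rescaled to 0..255 using the
#' dataset-wide minimum and maximum (all frames, all ROIs).
#'
#' @param frames list of frames, each a list with `shg` and `tpef`
#'   matrices.
#' @param bin_factor block size of the initial binning.
#' @return list with `frames` (per frame: `shg` and `tpef`
#'   [discretized_image()]s sharing the OR `mask`) and `skipped` (indices
#'   of frames dropped as degenerate, with reasons).
#' @export
radiomics_preprocess <- function(frames, bin_factor = 4L) {
  pre <- vector("list", length(frames))
  skipped <- character(0)
  for (i in seq_along(frames)) {
    res <- tryCatch({
      bs <- bin_image(frames[[i]]$shg, bin_factor)
      bt <- bin_image(frames[[i]]$tpef, bin_factor)
      mask <- build_foreground_mask(bs, bt)
      list(shg = background_renormalize(bs, mask),
           tpef = background_renormalize(bt, mask),
           mask = mask)
    }, error = function(e) conditionMessage(e))
    if (is.character(res)) {
      skipped[as.character(i)] <- res
      pre[i] <- list(NULL)
    } else pre[[i]] <- res
  }
  ok <- !vapply(pre, is.null, TRUE)
  rescale01 <- function(ms) {
    lo <- min(vapply(ms, min, 0)); hi <- max(vapply(ms, max, 0))
    if (hi == lo) stop2("degenerate dataset: constant modality")
    lapply(ms, function(m) round_half_away((m - lo) / (hi - lo) * 255))
  }
  shg8 <- rescale01(lapply(pre[ok], `[[`, "shg"))
  tpef8 <- rescale01(lapply(pre[ok], `[[`, "tpef"))
  out <- vector("list", length(frames))
  j <- 0L
  for (i in which(ok)) {
    j <- j + 1L
    out[[i]] <- list(
      shg = discretized_image(shg8[[j]], pre[[i]]$mask, "SHG"),
      tpef = discretized_image(tpef8[[j]], pre[[i]]$mask, "TPEF")
    )
  }
  list(frames = out, skipped = skipped)
}

## ---- texture matrices ----------------------------------------------------

texture_directions <- function() {
  list(c(0L, 1L), c(1L, 0L), c(1L, 1L), c(1L, -1L))
}

#' Gray-level co-occurrence matrices
#'
#' Co-occurrence counts of 1-based gray levels over masked pixel pairs at
#' the given offset distance, one symmetrized and normalized matrix per
#' direction (horizontal, vertical and both diagonals).
#'
#' @param x a [discretized_image()].
#' @param distance offset in pixels (default 1).
#' @return list of 256 x 256 probability matrices, one per direction.
#' @export
build_glcm <- function(x, distance = 1L) {
  g <- x$img + 1L
  msk <- x$mask
  nr <- nrow(g); nc <- ncol(g)
  out <- list()
  for (d in texture_directions()) {
    dr <- d[1] * distance; dc <- d[2] * distance
    rs <- seq_len(nr - abs(dr)); cs <- seq_len(nc - abs(dc))
    r1 <- if (dr >= 0) rs else rs + abs(dr)
    c1 <- if (dc >= 0) cs else cs + abs(dc)
    r2 <- r1 + dr; c2 <- c1 + dc
    m1 <- msk[r1, c1, drop = FALSE] & msk[r2, c2, drop = FALSE]
    ga <- g[r1, c1, drop = FALSE][m1]
    gb <- g[r2, c2, drop = FALSE][m1]
    cnt <- matrix(tabulate((ga - 1L) * RAD_NG + gb, RAD_NG * RAD_NG),
                  RAD_NG, RAD_NG, byrow = TRUE)
    cnt <- cnt + t(cnt)
    s <- sum(cnt)
    out[[length(out) + 1L]] <- if (s > 0) cnt / s else cnt
  }
  out
}

## Maximal same-level colinear masked runs, one level x run-length count
## matrix per direction.
#' Gray-level run-length matrices
#'
#' @param x a [discretized_image()].
#' @return list of count matrices (level x run length), one per direction.
#' @export
build_glrlm <- function(x) {
  g <- x$img + 1L
  v <- g
  v[!x$mask] <- NA
  nr <- nrow(v); nc <- ncol(v)
  maxlen <- max(nr, nc)
  runs_of <- function(lines) {
    m <- matrix(0, RAD_NG, maxlen)
    for (ln in lines) {
      r <- rle(as.vector(ln))
      keep <- !is.na(r$values)
      if (!any(keep)) next
      idx <- cbind(r$values[keep], r$lengths[keep])
      for (k in seq_len(nrow(idx)))
        m[idx[k, 1], idx[k, 2]] <- m[idx[k, 1], idx[k, 2]] + 1
    }
    m
  }
  rows_list <- lapply(seq_len(nr), function(r) v[r, ])
  cols_list <- lapply(seq_len(nc), function(c) v[, c])
  ## diagonals: constant r - c (45 deg down-right) and r + c
  rr <- row(v); cc <- col(v)
  d1 <- split(v, rr - cc)
  d2 <- split(v, rr + cc)
  list(runs_of(rows_list), runs_of(cols_list), runs_of(d1), runs_of(d2))
}

#' Gray-level size-zone matrix
#'
#' Zones are 8-connected components of equal-level masked pixels; the
#' matrix counts zones by level and size.
#'
#' @param x a [discretized_image()].
#' @return count matrix (level x zone size).
#' @export
build_glszm <- function(x) {
  g <- x$img + 1L
  mask <- x$mask
  nr <- nrow(g); nc <- ncol(g)
  ## all-levels-at-once 8-connected components by min-label propagation
  ## with pointer jumping (labels are pixel linear indices)
  lab <- matrix(seq_len(nr * nc), nr, nc)
  lab[!mask] <- 0L
  gz <- g
  gz[!mask] <- -1L
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
               c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  repeat {
    old <- lab
    for (d in offs) {
      nl <- shift_mat(lab, d[1], d[2])
      ng <- shift_mat(gz, d[1], d[2])
      upd <- mask & nl > 0 & ng == gz & nl < lab
      lab[upd] <- nl[upd]
    }
    sel <- lab > 0
    lab[sel] <- lab[lab[sel]]   # path compression
    lab[sel] <- lab[lab[sel]]
    if (identical(lab, old)) break
  }
  zl <- lab[mask]
  sizes <- tabulate(zl, nbins = nr * nc)
  roots <- which(sizes > 0)
  m <- matrix(0, RAD_NG, max(sizes))
  for (k in seq_along(roots))
    m[g[roots[k]], sizes[roots[k]]] <- m[g[roots[k]], sizes[roots[k]]] + 1
  m
}

## masked 8-neighbor mean at every pixel (NA where no masked neighbor)
neighbor_mean <- function(img, mask) {
  vm <- img * mask
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
               c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  ssum <- matrix(0, nrow(img), ncol(img))
  scnt <- matrix(0, nrow(img), ncol(img))
  for (d in offs) {
    ssum <- ssum + shift_mat(vm, d[1], d[2])
    scnt <- scnt + shift_mat(mask * 1, d[1], d[2])
  }
  out <- ssum / scnt
  out[scnt == 0] <- NA
  out
}

#' Neighborhood gray-tone difference matrix
#'
#' For each level: the number of masked pixels at that level (`n`), their
#' occupancy (`p`), and the summed absolute difference between the level
#' and the mean of each pixel's masked 8-neighborhood (`s`).
#'
#' @param x a [discretized_image()].
#' @return list with vectors `n`, `p`, `s` of length 256 and `nv`, the
#'   number of valid (neighbored) pixels.
#' @export
build_ngtdm <- function(x) {
  g <- x$img + 1L
  a <- neighbor_mean(g, x$mask)
  valid <- x$mask & !is.na(a)
  gv <- g[valid]
  av <- a[valid]
  n <- tabulate(gv, RAD_NG)
  s <- numeric(RAD_NG)
  agg <- rowsum(abs(gv - av), gv)
  s[as.integer(rownames(agg))] <- agg
  list(n = n, p = n / sum(n), s = s, nv = sum(n))
}

#' Neighboring gray-level dependence matrix
#'
#' Dependence of a masked pixel = number of its masked 8-neighbors whose
#' level differs from its own by at most `alpha` (default 0).
#'
#' @param x a [discretized_image()].
#' @param alpha coarseness tolerance.
#' @return count matrix (level x dependence k + 1, k in 0..8).
#' @export
build_ngldm <- function(x, alpha = 0L) {
  g <- x$img + 1L
  offs <- list(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1),
               c(0, 1), c(1, -1), c(1, 0), c(1, 1))
  dep <- matrix(0, nrow(g), ncol(g))
  for (d in offs) {
    ng <- shift_mat(g, d[1], d[2])
    nm <- shift_mat(x$mask * 1, d[1], d[2])
    dep <- dep + (nm == 1 & abs(ng - g) <= alpha)
  }
  gv <- g[x$mask]
  kv <- dep[x$mask]
  matrix(tabulate((gv - 1L) * 9L + kv + 1L, RAD_NG * 9L), RAD_NG, 9L,
         byrow = TRUE)
}

## ---- feature formulas ----------------------------------------------------

glcm_features_one <- function(p) {
  s <- sum(p)
  if (s == 0) {
    nm <- c("cm.joint.max", "cm.joint.avg", "cm.joint.var", "cm.joint.entr",
            "cm.diff.avg", "cm.diff.var", "cm.diff.entr", "cm.sum.avg",
            "cm.sum.var", "cm.sum.entr", "cm.energy", "cm.contrast",
            "cm.dissimilarity", "cm.inv.diff", "cm.inv.diff.norm",
            "cm.inv.diff.mom", "cm.inv.diff.mom.norm", "cm.corr",
            "cm.auto.corr", "cm.clust.tend", "cm.clust.shade",
            "cm.clust.prom")
    return(stats::setNames(rep(NA_real_, length(nm)), nm))
  }
  occ <- which(p > 0, arr.ind = TRUE)
  pv <- p[occ]
  iv <- occ[, 1]; jv <- occ[, 2]
  pi_m <- rowSums(p)
  mu_i <- sum(seq_len(RAD_NG) * pi_m)
  var_i <- sum((seq_len(RAD_NG) - mu_i)^2 * pi_m)
  mu <- sum(iv * pv)
  dvec <- abs(iv - jv)
  pd <- rowsum(pv, dvec)        # p(|i-j|)
  dlev <- as.numeric(rownames(pd))
  da <- sum(dlev * pd)
  svec <- iv + jv
  ps <- rowsum(pv, svec)
  slev <- as.numeric(rownames(ps))
  sa <- sum(slev * ps)
  corr <- if (var_i > 0)
    (sum(iv * jv * pv) - mu_i^2) / var_i else NA_real_
  c(cm.joint.max = max(pv),
    cm.joint.avg = mu,
    cm.joint.var = sum((iv - mu)^2 * pv),
    cm.joint.entr = -sum(pv * log2(pv)),
    cm.diff.avg = da,
    cm.diff.var = sum((dlev - da)^2 * pd),
    cm.diff.entr = -sum(pd * log2(pd)),
    cm.sum.avg = sa,
    cm.sum.var = sum((slev - sa)^2 * ps),
    cm.sum.entr = -sum(ps * log2(ps)),
    cm.energy = sum(pv^2),
    cm.contrast = sum((iv - jv)^2 * pv),
    cm.dissimilarity = sum(dvec * pv),
    cm.inv.diff = sum(pv / (1 + dvec)),
    cm.inv.diff.norm = sum(pv / (1 + dvec / RAD_NG)),
    cm.inv.diff.mom = sum(pv / (1 + dvec^2)),
    cm.inv.diff.mom.norm = sum(pv / (1 + dvec^2 / RAD_NG^2)),
    cm.corr = corr,
    cm.auto.corr = sum(iv * jv * pv),
    cm.clust.tend = sum((iv + jv - 2 * mu_i)^2 * pv),
    cm.clust.shade = sum((iv + jv - 2 * mu_i)^3 * pv),
    cm.clust.prom = sum((iv + jv - 2 * mu_i)^4 * pv))
}

## Shared run-type feature formulas for GLRLM (j = run length), GLSZM
## (j = zone size) and NGLDM (j = dependence + 1).  `m` is a count matrix
## level x j; `npix` the masked pixel count; `prefix` e.g. "rlm"; `jname`
## the j-axis tag used in feature names.
runtype_features <- function(m, npix, prefix,
                             short = "s", long = "l", axis = "r") {
  ns <- sum(m)
  nm <- function(x) paste0(prefix, ".", x)
  ## family-specific low/high gray-level names: lgre (runs), lgze (zones),
  ## lgce (dependence counts)
  lg <- paste0("lg", axis, "e"); hg <- paste0("hg", axis, "e")
  keys <- nm(c(paste0(short, axis, "e"), paste0(long, axis, "e"),
               lg, hg,
               paste0(short, axis, "lge"), paste0(short, axis, "hge"),
               paste0(long, axis, "lge"), paste0(long, axis, "hge"),
               "glnu", "glnu.norm", paste0(axis, "nu"),
               paste0(axis, "nu.norm"), paste0(axis, ".perc"),
               "gl.var", paste0(axis, ".var"), paste0(axis, ".entr")))
  if (ns == 0)
    return(stats::setNames(rep(NA_real_, length(keys)), keys))
  ivals <- seq_len(nrow(m))
  jvals <- seq_len(ncol(m))
  ri <- rowSums(m)
  rj <- colSums(m)
  p <- m / ns
  pocc <- p[p > 0]
  mu_i <- sum(ivals * ri) / ns
  mu_j <- sum(jvals * rj) / ns
  out <- c(
    sum(rj / jvals^2) / ns,
    sum(rj * jvals^2) / ns,
    sum(ri / ivals^2) / ns,
    sum(ri * ivals^2) / ns,
    sum(sweep(sweep(m, 1, ivals^2, "/"), 2, jvals^2, "/")) / ns,
    sum(sweep(sweep(m, 1, ivals^2, "*"), 2, jvals^2, "/")) / ns,
    sum(sweep(sweep(m, 1, ivals^2, "/"), 2, jvals^2, "*")) / ns,
    sum(sweep(sweep(m, 1, ivals^2, "*"), 2, jvals^2, "*")) / ns,
    sum(ri^2) / ns,
    sum(ri^2) / ns^2,
    sum(rj^2) / ns,
    sum(rj^2) / ns^2,
    ns / npix,
    sum((ivals - mu_i)^2 * ri) / ns,
    sum((jvals - mu_j)^2 * rj) / ns,
    -sum(pocc * log2(pocc))
  )
  stats::setNames(out, keys)
}

ngtdm_features <- function(nt) {
  p <- nt$p; s <- nt$s; nv <- nt$nv
  occ <- which(p > 0)
  np <- length(occ)
  if (nv == 0 || np == 0)
    return(c(ntg.coarseness = NA, ntg.contrast = NA, ntg.busyness = NA,
             ntg.complexity = NA, ntg.strength = NA))
  pi <- p[occ]; si <- s[occ]; gi <- occ
  den_coarse <- sum(pi * si)
  coarse <- if (den_coarse > 0) 1 / den_coarse else NA_real_
  if (np > 1) {
    dif2 <- outer(gi, gi, "-")^2
    pp <- outer(pi, pi)
    contrast <- sum(pp * dif2) / (np * (np - 1)) * sum(si) / nv
    busy_den <- sum(abs(outer(gi * pi, gi * pi, "-")))
    busy <- if (busy_den > 0) sum(pi * si) / busy_den else NA_real_
    num_cmp <- outer(pi * si, pi * si, "+")
    den_cmp <- outer(pi, pi, "+")
    cmplx <- sum(abs(outer(gi, gi, "-")) * num_cmp / den_cmp) / nv
    stren_num <- sum(den_cmp * dif2)
    stren <- if (sum(si) > 0) stren_num / sum(si) else NA_real_
  } else {
    contrast <- 0; busy <- NA_real_; cmplx <- 0
    stren <- if (sum(si) > 0) 0 else NA_real_
  }
  c(ntg.coarseness = coarse, ntg.contrast = contrast, ntg.busyness = busy,
    ntg.complexity = cmplx, ntg.strength = stren)
}

intensity_stats <- function(xv) {
  n <- length(xv)
  mu <- mean(xv)
  m2 <- mean((xv - mu)^2)
  sdv <- sqrt(m2)
  qs <- stats::quantile(xv, c(0.1, 0.25, 0.5, 0.75, 0.9), type = 7,
                        names = FALSE)
  sel <- xv >= qs[1] & xv <= qs[5]
  c(stat.mean = mu,
    stat.var = m2,
    stat.skew = if (sdv > 0) mean((xv - mu)^3) / sdv^3 else NA_real_,
    stat.kurt = if (sdv > 0) mean((xv - mu)^4) / m2^2 - 3 else NA_real_,
    stat.median = qs[3],
    stat.min = min(xv),
    stat.p10 = qs[1],
    stat.p90 = qs[5],
    stat.max = max(xv),
    stat.iqr = qs[4] - qs[2],
    stat.range = max(xv) - min(xv),
    stat.mad = mean(abs(xv - mu)),
    stat.rmad = mean(abs(xv[sel] - mean(xv[sel]))),
    stat.medad = mean(abs(xv - qs[3])),
    stat.cov = if (mu != 0) sdv / mu else NA_real_,
    stat.qcod = if (qs[4] + qs[2] != 0)
      (qs[4] - qs[2]) / (qs[4] + qs[2]) else NA_real_,
    stat.energy = sum(xv^2),
    stat.rms = sqrt(mean(xv^2)))
}

histogram_features <- function(xv) {
  g <- xv + 1L          # 1-based levels, as in the texture families
  n <- length(g)
  cnt <- tabulate(g, RAD_NG)
  p <- cnt / n
  lev <- seq_len(RAD_NG)
  mu <- sum(lev * p)
  m2 <- sum((lev - mu)^2 * p)
  sdv <- sqrt(m2)
  qs <- stats::quantile(g, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
  pocc <- p[p > 0]
  ## histogram gradient (central differences, one-sided at the edges)
  grad <- c(cnt[2] - cnt[1],
            (cnt[3:RAD_NG] - cnt[1:(RAD_NG - 2)]) / 2,
            cnt[RAD_NG] - cnt[RAD_NG - 1])
  c(ih.mean = mu,
    ih.var = m2,
    ih.skew = if (sdv > 0) sum((lev - mu)^3 * p) / sdv^3 else NA_real_,
    ih.kurt = if (sdv > 0) sum((lev - mu)^4 * p) / m2^2 - 3 else NA_real_,
    ih.median = qs[2],
    ih.min = min(g),
    ih.p10 = stats::quantile(g, 0.1, type = 7, names = FALSE),
    ih.p90 = stats::quantile(g, 0.9, type = 7, names = FALSE),
    ih.max = max(g),
    ih.mode = which.max(cnt),
    ih.iqr = qs[3] - qs[1],
    ih.range = max(g) - min(g),
    ih.qcod = if (qs[3] + qs[1] != 0)
      (qs[3] - qs[1]) / (qs[3] + qs[1]) else NA_real_,
    ih.entropy = -sum(pocc * log2(pocc)),
    ih.uniformity = sum(pocc^2),
    ih.max.grad = max(grad),
    ih.max.grad.gl = lev[which.max(grad)],
    ih.min.grad = min(grad),
    ih.min.grad.gl = lev[which.min(grad)])
}

ivh_features <- function(xv) {
  lo <- min(xv); hi <- max(xv)
  frac_at <- function(x) {
    thr <- lo + x * (hi - lo)
    mean(xv >= thr)
  }
  inten_at <- function(v) {
    ## largest intensity fraction reached by at least v of the pixels
    if (hi == lo) return(1)
    s <- sort(xv, decreasing = TRUE)
    g <- s[max(1L, ceiling(v * length(s)))]
    (g - lo) / (hi - lo)
  }
  c(ivh.V10 = frac_at(0.10), ivh.V90 = frac_at(0.90),
    ivh.I10 = inten_at(0.10), ivh.I90 = inten_at(0.90),
    ivh.V10minusV90 = frac_at(0.10) - frac_at(0.90))
}

local_intensity_peak <- function(img, mask, radius = 3) {
  pk <- which(img == max(img[mask]) & mask, arr.ind = TRUE)
  off <- expand.grid(dr = -radius:radius, dc = -radius:radius)
  off <- off[off$dr^2 + off$dc^2 <= radius^2, ]
  best <- -Inf
  for (k in seq_len(nrow(pk))) {
    rr <- pk[k, 1] + off$dr; cc <- pk[k, 2] + off$dc
    ok <- rr >= 1 & rr <= nrow(img) & cc >= 1 & cc <= ncol(img)
    best <- max(best, mean(img[cbind(rr[ok], cc[ok])]))
  }
  c(loc.peak.global = best)
}

morph_features <- function(img, mask) {
  area <- sum(mask)
  idx <- which(mask, arr.ind = TRUE)
  cen <- colMeans(idx)
  wsum <- sum(img[mask])
  com <- if (wsum > 0) {
    wcen <- c(sum(idx[, 1] * img[mask]), sum(idx[, 2] * img[mask])) / wsum
    sqrt(sum((cen - wcen)^2))
  } else NA_real_
  ## perimeter: count of 4-neighbor mask/background (or border) edges
  per <- 0
  for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1)))
    per <- per + sum(mask & !(shift_mat(mask * 1, d[1], d[2]) == 1))
  bbox <- (max(idx[, 1]) - min(idx[, 1]) + 1) *
    (max(idx[, 2]) - min(idx[, 2]) + 1)
  c(morph.av = area,
    morph.perim = per,
    morph.com = com,
    morph.area.dens.aabb = area / bbox)
}

#' Compute the radiomic feature panel of one discretized image
#'
#' Assembles every implemented feature family on the masked image and
#' returns a named vector keyed `"<MODALITY>::<Family>::<name>"` (e.g.
#' `"TPEF::Histogram::ih.max"`).  Undefined features are carried as NA.
#'
#' @param x a [discretized_image()].
#' @param glcm_distance co-occurrence offset (default 1).
#' @param peak_radius neighborhood radius (px) of the global intensity
#'   peak feature.
#' @return named numeric vector.
#' @export
compute_feature_panel <- function(x, glcm_distance = 1L, peak_radius = 3) {
  xv <- x$img[x$mask]
  fam <- list(
    Intensity = c(intensity_stats(xv),
                  local_intensity_peak(x$img, x$mask, peak_radius)),
    Histogram = histogram_features(xv),
    IVHistogram = ivh_features(xv),
    Morphological = morph_features(x$img, x$mask),
    GLCM = {
      per_dir <- lapply(build_glcm(x, glcm_distance), glcm_features_one)
      Reduce(`+`, per_dir) / length(per_dir)
    },
    GLRLM = {
      npx <- sum(x$mask)
      per_dir <- lapply(build_glrlm(x), runtype_features, npix = npx,
                        prefix = "rlm", short = "s", long = "l", axis = "r")
      Reduce(`+`, per_dir) / length(per_dir)
    },
    GLSZM = {
      m <- build_glszm(x)
      f <- runtype_features(m, sum(x$mask), "szm", "s", "l", "z")
      ## conventional GLSZM names: sze/lze and zs.* for the size axis
      names(f) <- sub("^szm\\.sze$", "szm.sze", names(f))
      names(f) <- sub("^szm\\.z\\.var$", "szm.zs.var", names(f))
      names(f) <- sub("^szm\\.z\\.entr$", "szm.zs.entr", names(f))
      names(f) <- sub("^szm\\.znu", "szm.zsnu", names(f))
      names(f) <- sub("^szm\\.z\\.perc$", "szm.z.perc", names(f))
      f
    },
    NGTDM = ngtdm_features(build_ngtdm(x)),
    NGLDM = {
      f <- runtype_features(build_ngldm(x), sum(x$mask),
                            "ngl", "l", "h", "d")
      names(f) <- sub("^ngl\\.d\\.var$", "ngl.dc.var", names(f))
      names(f) <- sub("^ngl\\.d\\.entr$", "ngl.dc.entr", names(f))
      names(f) <- sub("^ngl\\.dnu", "ngl.dcnu", names(f))
      names(f) <- sub("^ngl\\.d\\.perc$", "ngl.dc.perc", names(f))
      names(f) <- sub("^ngl\\.lgde$", "ngl.lgce", names(f))
      names(f) <- sub("^ngl\\.hgde$", "ngl.hgce", names(f))
      f
    }
  )
  out <- unlist(lapply(names(fam), function(fn) {
    v <- fam[[fn]]
    stats::setNames(v, paste0(x$modality, "::", fn, "::", names(v)))
  }))
  out
}
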