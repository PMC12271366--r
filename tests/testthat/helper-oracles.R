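## Independent brute-force oracles.  Everything here is written as plain
## loops and first-principles sums, deliberately sharing no code with the
## package implementations it checks.

## ---- thresholds ----------------------------------------------------------

o_renyi_threshold <- function(counts, alpha = 1) {
  p <- counts / sum(counts)
  n <- length(p)
  best_t <- NA
  best_h <- -Inf
  for (t in 0:(n - 2)) {
    pb <- p[1:(t + 1)]
    pa <- p[(t + 2):n]
    wb <- sum(pb); wa <- sum(pa)
    if (wb == 0 || wa == 0) next
    hb <- ha <- 0
    if (abs(alpha - 1) < 1e-12) {
      for (q in pb[pb > 0] / wb) hb <- hb - q * log(q)
      for (q in pa[pa > 0] / wa) ha <- ha - q * log(q)
    } else {
      sb <- sum((pb[pb > 0] / wb)^alpha)
      sa <- sum((pa[pa > 0] / wa)^alpha)
      hb <- log(sb) / (1 - alpha)
      ha <- log(sa) / (1 - alpha)
    }
    if (hb + ha > best_h) {
      best_h <- hb + ha
      best_t <- t
    }
  }
  best_t
}

o_li_threshold <- function(counts) {
  g <- seq_along(counts) - 1
  n <- length(counts)
  best_t <- NA
  best_e <- Inf
  for (t in 0:(n - 2)) {
    below <- g <= t
    wb <- sum(counts[below]); wf <- sum(counts[!below])
    if (wb == 0 || wf == 0) next
    mb <- sum(g[below] * counts[below]) / wb
    mf <- sum(g[!below] * counts[!below]) / wf
    eta <- 0
    for (i in which(below & counts > 0 & g > 0))
      eta <- eta - g[i] * counts[i] * log(max(mb, 1e-300))
    for (i in which(!below & counts > 0 & g > 0))
      eta <- eta - g[i] * counts[i] * log(max(mf, 1e-300))
    if (eta < best_e) {
      best_e <- eta
      best_t <- t
    }
  }
  best_t
}

## ---- circular range ------------------------------------------------------

## prefix-sum based shortest arc containing weight strictly > 1/2
o_range_bins <- function(f) {
  n <- length(f)
  best <- NA
  for (len in 1:n) {
    for (s in 1:n) {
      idx <- ((s - 1 + 0:(len - 1)) %% n) + 1
      if (sum(f[idx]) > 0.5 + 1e-12) {
        best <- len
        break
      }
    }
    if (!is.na(best)) break
  }
  best
}

## ---- texture matrices ----------------------------------------------------

o_glcm <- function(img, mask, distance, dir) {
  g <- img + 1L
  nr <- nrow(g); nc <- ncol(g)
  cnt <- matrix(0, 256, 256)
  for (r in 1:nr) for (c in 1:nc) {
    r2 <- r + dir[1] * distance; c2 <- c + dir[2] * distance
    if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
    if (!mask[r, c] || !mask[r2, c2]) next
    cnt[g[r, c], g[r2, c2]] <- cnt[g[r, c], g[r2, c2]] + 1
  }
  cnt <- cnt + t(cnt)
  if (sum(cnt) > 0) cnt / sum(cnt) else cnt
}

o_glrlm_dir <- function(img, mask, dir) {
  g <- img + 1L
  nr <- nrow(g); nc <- ncol(g)
  m <- matrix(0, 256, max(nr, nc))
  visited <- matrix(FALSE, nr, nc)
  for (r in 1:nr) for (c in 1:nc) {
    if (!mask[r, c] || visited[r, c]) next
    pr <- r - dir[1]; pc <- c - dir[2]
    ## only start a run at its first pixel
    if (pr >= 1 && pr <= nr && pc >= 1 && pc <= nc &&
        mask[pr, pc] && g[pr, pc] == g[r, c]) next
    len <- 0
    rr <- r; cc <- c
    while (rr >= 1 && rr <= nr && cc >= 1 && cc <= nc &&
           mask[rr, cc] && g[rr, cc] == g[r, c]) {
      visited[rr, cc] <- TRUE
      len <- len + 1
      rr <- rr + dir[1]; cc <- cc + dir[2]
    }
    m[g[r, c], len] <- m[g[r, c], len] + 1
  }
  m
}

o_glszm <- function(img, mask) {
  g <- img + 1L
  nr <- nrow(g); nc <- ncol(g)
  seen <- matrix(FALSE, nr, nc)
  pairs <- list()
  for (r in 1:nr) for (c in 1:nc) {
    if (!mask[r, c] || seen[r, c]) next
    ## BFS flood fill over 8-connected equal-level pixels
    queue <- list(c(r, c))
    seen[r, c] <- TRUE
    size <- 0
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      size <- size + 1
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        rr <- p[1] + dr; cc <- p[2] + dc
        if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
        if (seen[rr, cc] || !mask[rr, cc]) next
        if (g[rr, cc] != g[r, c]) next
        seen[rr, cc] <- TRUE
        queue[[length(queue) + 1]] <- c(rr, cc)
      }
    }
    pairs[[length(pairs) + 1]] <- c(g[r, c], size)
  }
  mx <- max(vapply(pairs, `[`, 1, 2))
  m <- matrix(0, 256, mx)
  for (p in pairs) m[p[1], p[2]] <- m[p[1], p[2]] + 1
  m
}

o_ngtdm <- function(img, mask) {
  g <- img + 1L
  nr <- nrow(g); nc <- ncol(g)
  n <- numeric(256); s <- numeric(256)
  for (r in 1:nr) for (c in 1:nc) {
    if (!mask[r, c]) next
    vals <- c()
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (mask[rr, cc]) vals <- c(vals, g[rr, cc])
    }
    if (length(vals) == 0) next
    n[g[r, c]] <- n[g[r, c]] + 1
    s[g[r, c]] <- s[g[r, c]] + abs(g[r, c] - mean(vals))
  }
  list(n = n, p = n / sum(n), s = s, nv = sum(n))
}

o_ngldm <- function(img, mask, alpha = 0) {
  g <- img + 1L
  nr <- nrow(g); nc <- ncol(g)
  m <- matrix(0, 256, 9)
  for (r in 1:nr) for (c in 1:nc) {
    if (!mask[r, c]) next
    k <- 0
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nr || cc < 1 || cc > nc) next
      if (mask[rr, cc] && abs(g[rr, cc] - g[r, c]) <= alpha) k <- k + 1
    }
    m[g[r, c], k + 1] <- m[g[r, c], k + 1] + 1
  }
  m
}

## ---- feature formulas (naive sums) ---------------------------------------

o_glcm_features <- function(p) {
  stopifnot(sum(p) > 0)
  ng <- nrow(p)
  jmax <- 0; javg <- 0; jentr <- 0; energy <- 0; contrast <- 0
  dissim <- 0; invd <- 0; invdn <- 0; invdm <- 0; invdmn <- 0
  autoc <- 0
  pd <- numeric(ng); ps <- numeric(2 * ng)
  pim <- rowSums(p)
  mui <- 0
  for (i in 1:ng) mui <- mui + i * pim[i]
  vari <- 0
  for (i in 1:ng) vari <- vari + (i - mui)^2 * pim[i]
  for (i in 1:ng) for (j in 1:ng) {
    v <- p[i, j]
    if (v == 0) next
    jmax <- max(jmax, v)
    javg <- javg + i * v
    jentr <- jentr - v * log2(v)
    energy <- energy + v^2
    contrast <- contrast + (i - j)^2 * v
    dissim <- dissim + abs(i - j) * v
    invd <- invd + v / (1 + abs(i - j))
    invdn <- invdn + v / (1 + abs(i - j) / ng)
    invdm <- invdm + v / (1 + (i - j)^2)
    invdmn <- invdmn + v / (1 + (i - j)^2 / ng^2)
    autoc <- autoc + i * j * v
    pd[abs(i - j) + 1] <- pd[abs(i - j) + 1] + v
    ps[i + j] <- ps[i + j] + v
  }
  jvar <- 0
  for (i in 1:ng) for (j in 1:ng)
    if (p[i, j] > 0) jvar <- jvar + (i - javg)^2 * p[i, j]
  da <- 0
  for (d in 0:(ng - 1)) da <- da + d * pd[d + 1]
  dvar <- 0; dentr <- 0
  for (d in 0:(ng - 1)) {
    if (pd[d + 1] > 0) {
      dvar <- dvar + (d - da)^2 * pd[d + 1]
      dentr <- dentr - pd[d + 1] * log2(pd[d + 1])
    }
  }
  sa <- 0
  for (s2 in 2:(2 * ng)) sa <- sa + s2 * ps[s2]
  svar <- 0; sentr <- 0
  for (s2 in 2:(2 * ng)) {
    if (ps[s2] > 0) {
      svar <- svar + (s2 - sa)^2 * ps[s2]
      sentr <- sentr - ps[s2] * log2(ps[s2])
    }
  }
  corr <- NA_real_
  if (vari > 0) corr <- (autoc - mui^2) / vari
  ct <- cs <- cp <- 0
  for (i in 1:ng) for (j in 1:ng) {
    if (p[i, j] == 0) next
    ct <- ct + (i + j - 2 * mui)^2 * p[i, j]
    cs <- cs + (i + j - 2 * mui)^3 * p[i, j]
    cp <- cp + (i + j - 2 * mui)^4 * p[i, j]
  }
  c(cm.joint.max = jmax, cm.joint.avg = javg, cm.joint.var = jvar,
    cm.joint.entr = jentr, cm.diff.avg = da, cm.diff.var = dvar,
    cm.diff.entr = dentr, cm.sum.avg = sa, cm.sum.var = svar,
    cm.sum.entr = sentr, cm.energy = energy, cm.contrast = contrast,
    cm.dissimilarity = dissim, cm.inv.diff = invd, cm.inv.diff.norm = invdn,
    cm.inv.diff.mom = invdm, cm.inv.diff.mom.norm = invdmn, cm.corr = corr,
    cm.auto.corr = autoc, cm.clust.tend = ct, cm.clust.shade = cs,
    cm.clust.prom = cp)
}

o_runtype_features <- function(m, npix, keys) {
  ns <- sum(m)
  stopifnot(ns > 0)
  ni <- nrow(m); nj <- ncol(m)
  sre <- lre <- lge <- hge <- srl <- srh <- lrl <- lrh <- 0
  for (i in 1:ni) for (j in 1:nj) {
    v <- m[i, j]
    if (v == 0) next
    sre <- sre + v / j^2; lre <- lre + v * j^2
    lge <- lge + v / i^2; hge <- hge + v * i^2
    srl <- srl + v / (i^2 * j^2); srh <- srh + v * i^2 / j^2
    lrl <- lrl + v * j^2 / i^2; lrh <- lrh + v * i^2 * j^2
  }
  ri <- rowSums(m); rj <- colSums(m)
  glnu <- sum(ri^2) / ns
  rlnu <- sum(rj^2) / ns
  mui <- 0; muj <- 0
  for (i in 1:ni) mui <- mui + i * ri[i] / ns
  for (j in 1:nj) muj <- muj + j * rj[j] / ns
  glv <- 0; rlv <- 0
  for (i in 1:ni) glv <- glv + (i - mui)^2 * ri[i] / ns
  for (j in 1:nj) rlv <- rlv + (j - muj)^2 * rj[j] / ns
  entr <- 0
  for (i in 1:ni) for (j in 1:nj) {
    q <- m[i, j] / ns
    if (q > 0) entr <- entr - q * log2(q)
  }
  stats::setNames(
    c(sre / ns, lre / ns, lge / ns, hge / ns, srl / ns, srh / ns,
      lrl / ns, lrh / ns, glnu, glnu / ns, rlnu, rlnu / ns, ns / npix,
      glv, rlv, entr),
    keys)
}

o_ngtdm_features <- function(nt) {
  p <- nt$p; s <- nt$s; nv <- nt$nv
  occ <- which(p > 0)
  np <- length(occ)
  den <- 0
  for (i in occ) den <- den + p[i] * s[i]
  coarse <- if (den > 0) 1 / den else NA_real_
  if (np <= 1) {
    return(c(ntg.coarseness = coarse, ntg.contrast = 0, ntg.busyness = NA,
             ntg.complexity = 0,
             ntg.strength = if (sum(s) > 0) 0 else NA))
  }
  con1 <- 0
  for (i in occ) for (j in occ) con1 <- con1 + p[i] * p[j] * (i - j)^2
  contrast <- con1 / (np * (np - 1)) * sum(s) / nv
  bden <- 0
  for (i in occ) for (j in occ) bden <- bden + abs(i * p[i] - j * p[j])
  busy <- if (bden > 0) den / bden else NA_real_
  cmplx <- 0
  for (i in occ) for (j in occ)
    cmplx <- cmplx + abs(i - j) * (p[i] * s[i] + p[j] * s[j]) /
      (p[i] + p[j])
  cmplx <- cmplx / nv
  stren <- 0
  for (i in occ) for (j in occ) stren <- stren + (p[i] + p[j]) * (i - j)^2
  stren <- if (sum(s) > 0) stren / sum(s) else NA_real_
  c(ntg.coarseness = coarse, ntg.contrast = contrast, ntg.busyness = busy,
    ntg.complexity = cmplx, ntg.strength = stren)
}

o_intensity_stats <- function(xv) {
  n <- length(xv)
  mu <- sum(xv) / n
  m2 <- sum((xv - mu)^2) / n
  qs <- stats::quantile(xv, c(0.1, 0.25, 0.5, 0.75, 0.9), type = 7,
                        names = FALSE)
  sel <- xv[xv >= qs[1] & xv <= qs[5]]
  c(stat.mean = mu, stat.var = m2,
    stat.skew = if (m2 > 0) (sum((xv - mu)^3) / n) / m2^1.5 else NA,
    stat.kurt = if (m2 > 0) (sum((xv - mu)^4) / n) / m2^2 - 3 else NA,
    stat.median = qs[3], stat.min = min(xv), stat.p10 = qs[1],
    stat.p90 = qs[5], stat.max = max(xv), stat.iqr = qs[4] - qs[2],
    stat.range = max(xv) - min(xv), stat.mad = sum(abs(xv - mu)) / n,
    stat.rmad = sum(abs(sel - mean(sel))) / length(sel),
    stat.medad = sum(abs(xv - qs[3])) / n,
    stat.cov = if (mu != 0) sqrt(m2) / mu else NA,
    stat.qcod = if (qs[4] + qs[2] != 0)
      (qs[4] - qs[2]) / (qs[4] + qs[2]) else NA,
    stat.energy = sum(xv^2), stat.rms = sqrt(sum(xv^2) / n))
}

o_histogram_features <- function(xv) {
  g <- xv + 1
  n <- length(g)
  cnt <- numeric(256)
  for (v in g) cnt[v] <- cnt[v] + 1
  p <- cnt / n
  mu <- 0
  for (i in 1:256) mu <- mu + i * p[i]
  m2 <- 0
  for (i in 1:256) m2 <- m2 + (i - mu)^2 * p[i]
  m3 <- m4 <- 0
  for (i in 1:256) {
    m3 <- m3 + (i - mu)^3 * p[i]
    m4 <- m4 + (i - mu)^4 * p[i]
  }
  qs <- stats::quantile(g, c(0.1, 0.25, 0.5, 0.75, 0.9), type = 7,
                        names = FALSE)
  entr <- 0; unif <- 0
  for (i in 1:256) if (p[i] > 0) {
    entr <- entr - p[i] * log2(p[i])
    unif <- unif + p[i]^2
  }
  grad <- numeric(256)
  grad[1] <- cnt[2] - cnt[1]
  grad[256] <- cnt[256] - cnt[255]
  for (i in 2:255) grad[i] <- (cnt[i + 1] - cnt[i - 1]) / 2
  c(ih.mean = mu, ih.var = m2,
    ih.skew = if (m2 > 0) m3 / m2^1.5 else NA,
    ih.kurt = if (m2 > 0) m4 / m2^2 - 3 else NA,
    ih.median = qs[3], ih.min = min(g), ih.p10 = qs[1], ih.p90 = qs[5],
    ih.max = max(g), ih.mode = which.max(cnt), ih.iqr = qs[4] - qs[2],
    ih.range = max(g) - min(g),
    ih.qcod = if (qs[4] + qs[2] != 0)
      (qs[4] - qs[2]) / (qs[4] + qs[2]) else NA,
    ih.entropy = entr, ih.uniformity = unif,
    ih.max.grad = max(grad), ih.max.grad.gl = which.max(grad),
    ih.min.grad = min(grad), ih.min.grad.gl = which.min(grad))
}

o_ivh_features <- function(xv) {
  lo <- min(xv); hi <- max(xv)
  vfrac <- function(x) {
    thr <- lo + x * (hi - lo)
    sum(xv >= thr) / length(xv)
  }
  ifrac <- function(v) {
    if (hi == lo) return(1)
    s <- sort(xv, decreasing = TRUE)
    (s[max(1, ceiling(v * length(s)))] - lo) / (hi - lo)
  }
  c(ivh.V10 = vfrac(0.1), ivh.V90 = vfrac(0.9),
    ivh.I10 = ifrac(0.1), ivh.I90 = ifrac(0.9),
    ivh.V10minusV90 = vfrac(0.1) - vfrac(0.9))
}

o_morph_features <- function(img, mask) {
  area <- 0; sr <- 0; sc <- 0; wr <- 0; wc <- 0; wtot <- 0; per <- 0
  nr <- nrow(mask); nc <- ncol(mask)
  rmin <- Inf; rmax <- -Inf; cmin <- Inf; cmax <- -Inf
  for (r in 1:nr) for (c in 1:nc) {
    if (!mask[r, c]) next
    area <- area + 1
    sr <- sr + r; sc <- sc + c
    wr <- wr + r * img[r, c]; wc <- wc + c * img[r, c]
    wtot <- wtot + img[r, c]
    rmin <- min(rmin, r); rmax <- max(rmax, r)
    cmin <- min(cmin, c); cmax <- max(cmax, c)
    for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
      rr <- r + d[1]; cc <- c + d[2]
      if (rr < 1 || rr > nr || cc < 1 || cc > nc || !mask[rr, cc])
        per <- per + 1
    }
  }
  com <- if (wtot > 0)
    sqrt((sr / area - wr / wtot)^2 + (sc / area - wc / wtot)^2) else NA
  c(morph.av = area, morph.perim = per, morph.com = com,
    morph.area.dens.aabb = area / ((rmax - rmin + 1) * (cmax - cmin + 1)))
}

o_local_peak <- function(img, mask, radius = 3) {
  mx <- -Inf
  for (r in 1:nrow(img)) for (c in 1:ncol(img))
    if (mask[r, c]) mx <- max(mx, img[r, c])
  best <- -Inf
  for (r in 1:nrow(img)) for (c in 1:ncol(img)) {
    if (!mask[r, c] || img[r, c] != mx) next
    vals <- c()
    for (dr in -radius:radius) for (dc in -radius:radius) {
      if (dr^2 + dc^2 > radius^2) next
      rr <- r + dr; cc <- c + dc
      if (rr < 1 || rr > nrow(img) || cc < 1 || cc > ncol(img)) next
      vals <- c(vals, img[rr, cc])
    }
    best <- max(best, mean(vals))
  }
  c(loc.peak.global = best)
}

## Full oracle feature panel keyed like compute_feature_panel().
o_feature_panel <- function(x) {
  img <- x$img; mask <- x$mask
  xv <- img[mask]
  dirs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
  glcm_f <- Reduce(`+`, lapply(dirs, function(d)
    o_glcm_features(o_glcm(img, mask, 1, d)))) / 4
  rlm_keys <- c("rlm.sre", "rlm.lre", "rlm.lgre", "rlm.hgre", "rlm.srlge",
                "rlm.srhge", "rlm.lrlge", "rlm.lrhge", "rlm.glnu",
                "rlm.glnu.norm", "rlm.rnu", "rlm.rnu.norm", "rlm.r.perc",
                "rlm.gl.var", "rlm.r.var", "rlm.r.entr")
  rlm_f <- Reduce(`+`, lapply(dirs, function(d)
    o_runtype_features(o_glrlm_dir(img, mask, d), sum(mask),
                       rlm_keys))) / 4
  szm_keys <- c("szm.sze", "szm.lze", "szm.lgze", "szm.hgze", "szm.szlge",
                "szm.szhge", "szm.lzlge", "szm.lzhge", "szm.glnu",
                "szm.glnu.norm", "szm.zsnu", "szm.zsnu.norm", "szm.z.perc",
                "szm.gl.var", "szm.zs.var", "szm.zs.entr")
  szm_f <- o_runtype_features(o_glszm(img, mask), sum(mask), szm_keys)
  ngl_keys <- c("ngl.lde", "ngl.hde", "ngl.lgce", "ngl.hgce", "ngl.ldlge",
                "ngl.ldhge", "ngl.hdlge", "ngl.hdhge", "ngl.glnu",
                "ngl.glnu.norm", "ngl.dcnu", "ngl.dcnu.norm", "ngl.dc.perc",
                "ngl.gl.var", "ngl.dc.var", "ngl.dc.entr")
  ngl_f <- o_runtype_features(o_ngldm(img, mask), sum(mask), ngl_keys)
  fam <- list(
    Intensity = c(o_intensity_stats(xv), o_local_peak(img, mask)),
    Histogram = o_histogram_features(xv),
    IVHistogram = o_ivh_features(xv),
    Morphological = o_morph_features(img, mask),
    GLCM = glcm_f,
    GLRLM = rlm_f,
    GLSZM = szm_f,
    NGTDM = o_ngtdm_features(o_ngtdm(img, mask)),
    NGLDM = ngl_f
  )
  unlist(lapply(names(fam), function(fn)
    stats::setNames(fam[[fn]],
                    paste0(x$modality, "::", fn, "::", names(fam[[fn]])))))
}
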