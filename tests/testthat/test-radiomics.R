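test_that("radiomics preprocessing is renormalized and endpoint-exact", {
  pr <- phenotype_presets()
  frames <- lapply(1:3, function(i) generate_image(pr$border, 128,
                                                   seed = 40 + i))
  rp <- radiomics_preprocess(frames, bin_factor = 4)
  expect_equal(length(rp$skipped), 0)
  imgs <- unlist(lapply(rp$frames, function(f) as.vector(f$shg$img)))
  expect_equal(max(imgs), 255)   # dataset-wide max maps to 255
  expect_true(all(imgs >= 0 & imgs == floor(imgs)))
  ## doubling one frame's raw intensities leaves its result unchanged up
  ## to requantization (background renormalization removes the scale)
  f2 <- frames
  f2[[2]]$shg <- frames[[2]]$shg * 2
  f2[[2]]$tpef <- frames[[2]]$tpef * 2
  rp2 <- radiomics_preprocess(f2, bin_factor = 4)
  expect_lte(max(abs(rp2$frames[[2]]$shg$img - rp$frames[[2]]$shg$img)), 1)
  ## constant frames are flagged and skipped, not fatal
  f3 <- frames
  f3[[1]]$shg <- matrix(7, 128, 128)
  f3[[1]]$tpef <- matrix(7, 128, 128)
  rp3 <- radiomics_preprocess(f3, bin_factor = 4)
  expect_true("1" %in% names(rp3$skipped))
  expect_null(rp3$frames[[1]])
})

test_that("GLCM construction matches enumeration on toy rasters", {
  ## constant masked region: single co-occurrence cell
  xc <- discretized_image(matrix(7L, 6, 6), matrix(TRUE, 6, 6), "SHG")
  fc <- compute_feature_panel(xc)
  expect_equal(unname(fc["SHG::GLCM::cm.joint.max"]), 1)
  ## strict checkerboard, horizontal direction: only (0,1)/(1,0) mass
  cb <- outer(1:6, 1:6, function(r, c) (r + c) %% 2)
  xcb <- discretized_image(cb, matrix(TRUE, 6, 6), "SHG")
  g1 <- build_glcm(xcb)[[1]]   # horizontal
  expect_equal(g1[1, 2] + g1[2, 1], 1)
  expect_equal(g1[1, 1] + g1[2, 2], 0)
  ## arbitrary toys equal the brute-force double loop
  for (x in random_toys(6, seed = 21)) {
    imp <- build_glcm(x)
    dirs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
    for (k in 1:4) {
      expect_equal(imp[[k]], o_glcm(x$img, x$mask, 1, dirs[[k]]),
                   tolerance = 1e-12)
    }
  }
})

test_that("zone, run, tone-difference and dependence matrices match oracles", {
  ## L-shaped single-level region: one zone of size 7
  img <- matrix(0L, 6, 6)
  msk <- matrix(FALSE, 6, 6)
  img[2:5, 2] <- 3L; img[5, 3:5] <- 3L
  msk[2:5, 2] <- TRUE; msk[5, 3:5] <- TRUE
  m <- build_glszm(discretized_image(img, msk, "SHG"))
  expect_equal(m[4, 7], 1)
  expect_equal(sum(m), 1)
  ## NGTDM complexity of a constant region is zero
  xc <- discretized_image(matrix(9L, 5, 5), matrix(TRUE, 5, 5), "SHG")
  expect_equal(unname(compute_feature_panel(xc)["SHG::NGTDM::ntg.complexity"]),
               0)
  for (x in random_toys(6, seed = 33)) {
    expect_equal(build_glszm(x), o_glszm(x$img, x$mask), tolerance = 1e-12)
    impl_r <- build_glrlm(x)
    dirs <- list(c(0, 1), c(1, 0), c(1, 1), c(1, -1))
    for (k in 1:4) {
      o <- o_glrlm_dir(x$img, x$mask, dirs[[k]])
      ii <- impl_r[[k]]
      expect_equal(ii[, seq_len(max(which(colSums(o) > 0)))],
                   o[, seq_len(max(which(colSums(o) > 0)))],
                   tolerance = 1e-12)
      expect_equal(sum(ii), sum(o))
    }
    nt <- build_ngtdm(x); ot <- o_ngtdm(x$img, x$mask)
    expect_equal(nt$n, ot$n)
    expect_equal(nt$s, ot$s, tolerance = 1e-9)
    expect_equal(build_ngldm(x), o_ngldm(x$img, x$mask), tolerance = 1e-12)
  }
})

test_that("degenerate single-level regions yield flagged, defined values", {
  xc <- discretized_image(matrix(7L, 8, 8), matrix(TRUE, 8, 8), "SHG")
  fc <- compute_feature_panel(xc)
  expect_equal(unname(fc["SHG::Histogram::ih.qcod"]), 0)
  expect_equal(unname(fc["SHG::IVHistogram::ivh.V90"]), 1)
  expect_true(is.na(fc["SHG::GLCM::cm.corr"]))   # zero marginal variance
  ## a 2x2 constant block has a single dependence cell: entropy 0
  x2 <- discretized_image(matrix(7L, 2, 2), matrix(TRUE, 2, 2), "SHG")
  expect_equal(unname(compute_feature_panel(x2)["SHG::NGLDM::ngl.dc.entr"]),
               0)
})

test_that("intensity-volume histogram matches direct counting on a ramp", {
  ramp <- matrix(rep(0:255, length.out = 16 * 16), 16, 16)
  x <- discretized_image(ramp, matrix(TRUE, 16, 16), "SHG")
  v90 <- compute_feature_panel(x)["SHG::IVHistogram::ivh.V90"]
  expect_equal(unname(v90), sum(ramp >= 0.9 * 255) / 256)
  ## morph.com is zero for a symmetric intensity pattern
  sym <- matrix(0L, 9, 9); sym[5, 5] <- 100L
  sym[4, 5] <- sym[6, 5] <- sym[5, 4] <- sym[5, 6] <- 40L
  xs <- discretized_image(sym, matrix(TRUE, 9, 9), "SHG")
  expect_equal(unname(compute_feature_panel(xs)["SHG::Morphological::morph.com"]),
               0, tolerance = 1e-12)
})

test_that("every panel feature matches the brute-force oracle on toys", {
  ## a quick spot check here; the full 50-toy sweep runs in the
  ## acceptance suite
  for (x in random_toys(8, seed = 55)) {
    imp <- compute_feature_panel(x)
    orc <- o_feature_panel(x)
    expect_setequal(names(imp), names(orc))
    orc <- orc[names(imp)]
    nas <- is.na(imp)
    expect_equal(nas, is.na(orc))
    rel <- abs(imp[!nas] - orc[!nas]) / pmax(abs(orc[!nas]), 1e-12)
    expect_lt(max(rel), 1e-9)
  }
})
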