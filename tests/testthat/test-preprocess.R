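test_that("Frangi vesselness enhances ridges and vanishes on flat input", {
  expect_equal(max(frangi_vesselness(matrix(5, 64, 64))), 0)
  expect_error(frangi_vesselness(matrix(1, 10, 10), scales_px = 0.2),
               "0.5 px")
  ## bright ridge outscores an equal-intensity circular blob at its center
  ridge <- matrix(0, 96, 96)
  ridge[47:50, 10:86] <- 200
  blob <- matrix(0, 96, 96)
  xy <- expand.grid(r = 1:96, c = 1:96)
  inside <- (xy$r - 48)^2 + (xy$c - 48)^2 <= 2^2
  blob[cbind(xy$r[inside], xy$c[inside])] <- 200
  for (s in c(1.8, 4.9, 8)) {
    vr <- frangi_vesselness(ridge, scales_px = s)
    vb <- frangi_vesselness(blob, scales_px = s)
    expect_gt(mean(vr[48, 20:76]), vb[48, 48])
  }
  ## response invariant under 90-degree rotation of an isotropic pattern
  rings <- matrix(0, 97, 97)
  for (r in 1:97) for (c in 1:97)
    rings[r, c] <- 100 * (1 + sin(sqrt((r - 49)^2 + (c - 49)^2)))
  v1 <- frangi_vesselness(rings)
  v2 <- frangi_vesselness(t(rings)[, 97:1])   # 90-degree rotation
  v2back <- t(v2[, 97:1])
  rel <- abs(v1 - v2back) / max(v1)
  expect_lt(max(rel), 0.01)
})

test_that("maximum Renyi entropy threshold equals the brute-force scan", {
  h <- integer(256); h[51] <- 100; h[201] <- 100
  t2 <- max_entropy_threshold(h)
  expect_true(t2 >= 50 && t2 < 200)
  for (i in 1:40) {
    counts <- random_histogram(64, seed = i)
    for (a in c(0.5, 1, 2)) {
      expect_equal(max_entropy_threshold(counts, a),
                   o_renyi_threshold(counts, a),
                   info = sprintf("hist %d order %.1f", i, a))
    }
  }
  ## order 1 equals the Kapur maximizer on a small 8-level histogram
  h8 <- c(10, 40, 5, 0, 2, 30, 25, 8)
  expect_equal(max_entropy_threshold(h8, 1), o_renyi_threshold(h8, 1))
  expect_error(max_entropy_threshold(c(0, 5, 0)), "degenerate")
})

test_that("Li threshold agrees with brute-force cross-entropy minimization", {
  ## two well-separated modes (levels 40..59 and 180..219): the threshold
  ## separates them
  h <- integer(256); h[41:60] <- 50; h[181:220] <- 30
  tl <- li_threshold(h)
  expect_true(tl >= 59 && tl < 180)
  for (i in 1:40) {
    counts <- random_histogram(64, seed = 1000 + i)
    expect_lte(abs(li_threshold(counts) - o_li_threshold(counts)), 1)
  }
  ## shift equivariance (away from the origin, where the log means flatten)
  base <- integer(256); base[81:90] <- 20; base[171:190] <- 35
  t0 <- li_threshold(base)
  shifted <- c(integer(30), base)[1:256]
  expect_lte(abs(li_threshold(shifted) - (t0 + 30)), 1)
})

test_that("foreground masks OR the per-channel Li masks", {
  set.seed(11)
  shg <- matrix(rpois(64^2, 10), 64)
  shg[20:40, 20:40] <- shg[20:40, 20:40] + 200
  tpef_flat <- matrix(rpois(64^2, 10), 64)
  m <- build_foreground_mask(shg, tpef_flat)
  ## the bright square is captured
  expect_gt(mean(m[20:40, 20:40]), 0.95)
  ## mask area always >= each single-channel mask area
  for (i in 1:5) {
    a <- matrix(rpois(32^2, 20) + rep(c(0, 60), each = 512), 32)
    b <- matrix(rpois(32^2, 20) + rep(c(80, 0), each = 512), 32)
    mm <- build_foreground_mask(a, b)
    expect_gte(sum(mm), sum(nlomscar:::li_mask(a)))
    expect_gte(sum(mm), sum(nlomscar:::li_mask(b)))
  }
  expect_error(build_foreground_mask(matrix(0, 4, 4), matrix(0, 5, 5)),
               "co-registered")
})

test_that("binning averages blocks and conserves total intensity", {
  expect_equal(bin_image(matrix(3.7, 8, 8), 4), matrix(3.7, 2, 2))
  expect_equal(bin_image(matrix(0:15, 4, 4), 4), matrix(7.5, 1, 1))
  set.seed(2)
  m <- matrix(runif(64 * 64), 64)
  b <- bin_image(m, 4)
  expect_equal(sum(b) * 16, sum(m), tolerance = 1e-9)
  ## block identity: first output pixel is the mean of the first block
  expect_equal(b[1, 1], mean(m[1:4, 1:4]))
  expect_error(bin_image(matrix(0, 5, 5), 4), "divisible")
})

test_that("background renormalization is idempotent and scale invariant", {
  set.seed(3)
  img <- matrix(runif(400, 5, 15), 20)
  mask <- matrix(FALSE, 20, 20); mask[1:5, 1:5] <- TRUE
  rn <- background_renormalize(img, mask)
  expect_equal(mean(rn[!mask]), 1, tolerance = 1e-12)
  expect_equal(background_renormalize(rn, mask), rn, tolerance = 1e-12)
  for (c in c(0.1, 3, 42)) {
    expect_equal(background_renormalize(img * c, mask), rn,
                 tolerance = 1e-12)
  }
  expect_error(background_renormalize(img, matrix(TRUE, 20, 20)),
               "empty background")
})

test_that("segmentation pipelines share stack thresholds and stay specific", {
  pr <- phenotype_presets()
  ph0 <- pr$muscle
  ph0$collagen_fiber_count <- 0L
  frames <- c(lapply(1:3, function(i) generate_image(pr$muscle, 128,
                                                     seed = 200 + i)),
              list(generate_image(ph0, 128, seed = 999)))
  seg <- segment_collagen_pipeline(lapply(frames, `[[`, "shg"))
  ## a zero-collagen frame in the stack stays almost empty
  expect_lt(mean(seg$binary[[4]]), 0.02)
  ## duplicate frames give identical binaries (shared stack threshold)
  dup <- segment_tpef_pipeline(list(frames[[1]]$tpef, frames[[1]]$tpef))
  expect_identical(dup$binary[[1]], dup$binary[[2]])
  ## a single rendered thick fiber is recovered: overlap >= 80% of the
  ## ground-truth footprint
  fx <- fixture_straight_fiber()
  footprint <- fx$canvas >= 200   # half of the 400-count ridge peak
  bin <- fx$seg$binary[[1]] == 1
  expect_gte(sum(bin & footprint) / sum(footprint), 0.8)
})
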