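test_that("collagen amount ratios follow their defining arithmetic", {
  expect_equal(collagen_intensity_ratio(matrix(30, 4, 4), matrix(90, 4, 4)),
               0.25)
  expect_equal(collagen_intensity_ratio(matrix(5, 4, 4), matrix(5, 4, 4)),
               0.5)
  expect_equal(collagen_intensity_ratio(matrix(0, 4, 4), matrix(9, 4, 4)), 0)
  expect_error(collagen_intensity_ratio(matrix(0, 4, 4), matrix(0, 4, 4)),
               "all zero")
  m40 <- matrix(0, 20, 20); m40[1:2, 1:20] <- 1
  m120 <- matrix(0, 20, 20); m120[5:10, 1:20] <- 1
  expect_equal(collagen_segmentation_ratio(m40, m120), 40 / 160)
  expect_equal(collagen_segmentation_ratio(m40, m40), 0.5)
  expect_equal(collagen_segmentation_ratio(matrix(0, 4, 4), m40[1:4, 1:4]),
               0)
  expect_error(collagen_segmentation_ratio(matrix(0, 4, 4),
                                           matrix(0, 4, 4)), "empty")
})

test_that("fiber tracer recovers isolated straight fibers and arcs", {
  ## empty input
  expect_equal(length(trace_fibers(matrix(0, 32, 32))), 0)
  ## straight rendered fiber through the real segmentation pipeline
  fx <- fixture_straight_fiber()
  fibers <- trace_fibers(fx$seg$binary[[1]], fx$seg$enhanced[[1]],
                         pixel_size_um = 1)
  expect_equal(length(fibers), 1)
  f <- fibers[[1]]
  expect_lt(abs(f$length_um - fx$truth$length_px) / fx$truth$length_px, 0.15)
  expect_lte(abs(f$width_um - fx$truth$width_px), 1)
  expect_gte(f$straightness, 0.98)
  dang <- abs(f$angle_deg - fx$truth$angle_deg)
  expect_lt(min(dang, 180 - dang), 5)
  ## a semicircular arc has straightness 2/pi (chord/arc geometry)
  th <- seq(0, pi, length.out = 400)
  arcm <- matrix(0, 200, 200)
  for (i in seq_along(th)) {
    r <- round(100 + 60 * sin(th[i])); c <- round(100 + 60 * cos(th[i]))
    arcm[(r - 1):(r + 1), (c - 1):(c + 1)] <- 1
  }
  fa <- trace_fibers(arcm, pixel_size_um = 1)
  expect_equal(length(fa), 1)
  expect_lt(abs(fa[[1]]$straightness - 2 / pi), 0.05)
})

test_that("fiber morphology summary matches two-pass moments", {
  mk <- function(len, wid, str) {
    structure(list(length_um = len, width_um = wid, straightness = str,
                   angle_deg = 0), class = "fiber_record")
  }
  two <- list(mk(10, 3, 0.9), mk(30, 5, 1))
  s <- fiber_morphology_summary(two)
  expect_equal(unname(s["fiber.length.avg"]), 20)
  expect_equal(unname(s["fiber.length.std"]), 10)   # population sd
  one <- fiber_morphology_summary(list(mk(12, 4, 0.95)))
  expect_equal(unname(one["fiber.length.std"]), 0)
  empty <- fiber_morphology_summary(list())
  expect_equal(unname(empty["fiber.count"]), 0)
  expect_true(all(is.na(empty[-1])))
  ## against an independent two-pass computation on random records
  set.seed(8)
  fl <- lapply(1:17, function(i) mk(runif(1, 5, 60), runif(1, 2, 6),
                                    runif(1, 0.6, 1)))
  s2 <- fiber_morphology_summary(fl)
  lens <- vapply(fl, function(f) f$length_um, 1)
  expect_equal(unname(s2["fiber.length.avg"]), sum(lens) / 17)
  expect_equal(unname(s2["fiber.length.std"]),
               sqrt(sum((lens - mean(lens))^2) / 17))
})

test_that("directionality histograms respect the orientation convention", {
  ## structures along y (vertical grating varying along x) peak at 90 deg
  x <- matrix(rep(sin(2 * pi * (1:128) / 8), each = 128), 128, 128)
  h <- directionality_histogram(x + with_seed_test(1,
    matrix(rnorm(128^2, 0, 0.01), 128)))
  expect_lte(min(abs(which.max(h) - 1 - 90), 180 - abs(which.max(h) - 1 - 90)), 2)
  expect_equal(sum(h), 1, tolerance = 1e-12)
  ## rotating a grating moves the argmax by the same angle: structures at
  ## `ang` have their wave vector at `ang - 90`
  xy <- expand.grid(r = 1:160, c = 1:160)
  for (ang in c(0, 30, 60, 120)) {
    k <- (ang - 90) * pi / 180
    g <- matrix(sin(2 * pi * (xy$c * cos(k) + xy$r * sin(k)) / 9), 160, 160)
    hh <- directionality_histogram(g)
    d <- abs(which.max(hh) - 1 - ang)
    expect_lte(min(d, 180 - d), 2)
  }
  ## white noise is isotropic: doubled-angle MVL near zero
  mv <- mean(vapply(1:10, function(s) {
    n <- with_seed_test(100 + s, matrix(rnorm(128^2), 128))
    circular_summary(directionality_histogram(n))$mvl_axial
  }, 1))
  expect_lt(mv, 0.1)
  expect_error(directionality_histogram(matrix(4, 32, 32)), "constant")
})

test_that("fiber angle histograms bin and normalize correctly", {
  mk <- function(a) structure(list(length_um = 20, width_um = 4,
                                   straightness = 1, angle_deg = a),
                              class = "fiber_record")
  h45 <- fiber_angle_histogram(list(mk(45.2), mk(45.7)))
  expect_equal(which.max(h45) - 1, 45)
  expect_equal(sum(h45 > 0), 1)
  h2 <- fiber_angle_histogram(list(mk(0.5), mk(90.5)))
  expect_equal(unname(h2[c(1, 91)]), c(0.5, 0.5), ignore_attr = TRUE)
  set.seed(4)
  hr <- fiber_angle_histogram(lapply(runif(50, 0, 180), mk))
  expect_equal(sum(hr), 1, tolerance = 1e-12)
  expect_error(fiber_angle_histogram(list()), "no fibers")
})

test_that("circular statistics reproduce their closed forms", {
  ## delta histogram: MVL 1, range one bin
  f <- numeric(180); f[46] <- 1
  s <- circular_summary(f)
  expect_equal(s$mvl, 1, tolerance = 1e-12)
  expect_equal(s$range_bins, 1)
  expect_equal(s$theta_bar, 45 * pi / 180, tolerance = 1e-9)
  ## uniform: literal first-moment MVL is 2/pi in the continuum, not 0
  su <- circular_summary(rep(1 / 180, 180))
  expect_equal(su$mvl, 0.6366, tolerance = 1e-3)
  expect_equal(su$range_bins, 91)
  expect_equal(su$range_rad, 91 * pi / 180, tolerance = 1e-12)
  expect_equal(su$mvl_axial, 0, tolerance = 1e-9)
  ## equal mass at 0 and 90 degrees
  two <- numeric(180); two[1] <- 0.5; two[91] <- 0.5
  st <- circular_summary(two)
  expect_equal(st$X, 0.5, tolerance = 1e-9)
  expect_equal(st$Y, 0.5, tolerance = 1e-9)
  expect_equal(st$mvl, sqrt(0.5), tolerance = 1e-6)
  expect_error(circular_summary(rep(1 / 90, 180)), "not normalized")
})

test_that("the range statistic matches the prefix-sum oracle", {
  set.seed(6)
  for (i in 1:200) {
    n <- sample(c(12, 36, 180), 1)
    f <- rexp(n)
    if (runif(1) < 0.3) f[sample(n, n %/% 2)] <- 0
    if (all(f == 0)) f[1] <- 1
    f <- f / sum(f)
    expect_equal(circular_summary(f)$range_bins, o_range_bins(f),
                 info = paste("case", i))
  }
})

test_that("circular summary is equivariant under histogram rotation", {
  set.seed(7)
  ## literal first-moment statistics: equivariant for a concentrated
  ## histogram that never straddles the axial wrap point
  f <- numeric(180)
  f[40:70] <- dnorm(40:70, 55, 6)
  f <- f / sum(f)
  s0 <- circular_summary(f)
  for (k in c(-30, 20, 60)) {
    fk <- f[((0:179 - k) %% 180) + 1]
    sk <- circular_summary(fk)
    expect_equal(sk$mvl, s0$mvl, tolerance = 0.02)
    d <- abs(sk$theta_bar - ((s0$theta_bar + k * pi / 180) %% pi))
    expect_lt(min(d, pi - d), 0.03)
    expect_equal(sk$range_bins, s0$range_bins)
  }
  ## the doubled-angle diagnostic is exactly equivariant for any histogram
  g <- rexp(180); g <- g / sum(g)
  sg <- circular_summary(g)
  for (k in c(13, 60, 121)) {
    gk <- g[((0:179 - k) %% 180) + 1]
    sk <- circular_summary(gk)
    expect_equal(sk$mvl_axial, sg$mvl_axial, tolerance = 1e-9)
    expect_equal(sk$range_bins, sg$range_bins)
  }
})

test_that("axial mismatch wraps at the half-turn", {
  s <- function(t) list(theta_bar = t)
  expect_equal(angle_mismatch(s(0.7), s(0.7)), 0)
  expect_equal(angle_mismatch(s(0), s(pi / 2)), pi / 2)
  expect_equal(angle_mismatch(s(10 * pi / 180), s(170 * pi / 180)),
               20 * pi / 180, tolerance = 1e-9)
})

test_that("the conventional feature vector has the full 16-feature schema", {
  fx <- fixture_straight_fiber()
  bin <- fx$seg$binary[[1]]
  fibers <- trace_fibers(bin, fx$seg$enhanced[[1]], pixel_size_um = 1)
  tp <- with_seed_test(12, matrix(rpois(256^2, 50), 256))
  tp[100:150, ] <- tp[100:150, ] + 300
  v <- conventional_feature_vector(fx$noisy, tp, bin,
                                   nlomscar:::li_mask(tp) * 1, fibers)
  expect_equal(names(v), conventional_feature_names())
  expect_equal(length(v), 16)
  expect_true(v["collagen.intensity"] >= 0 && v["collagen.intensity"] <= 1)
  ## all-zero SHG: C_I = 0 and fiber count 0 with missing-value markers
  z <- conventional_feature_vector(matrix(0, 64, 64), matrix(5, 64, 64),
                                   matrix(0, 64, 64),
                                   matrix(1, 64, 64), list())
  expect_equal(unname(z["collagen.intensity"]), 0)
  expect_equal(unname(z["fiber.count"]), 0)
  expect_true(is.na(z["ctfire.mvl"]))
})
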