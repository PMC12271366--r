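test_that("kernel density estimates integrate to one and track the truth", {
  x <- with_seed_test(1, rnorm(2000))
  kd <- kde_estimate(x, grid = seq(-4, 4, length.out = 801))
  expect_lt(max(abs(kd$y[kd$x >= -3 & kd$x <= 3] -
                      dnorm(kd$x[kd$x >= -3 & kd$x <= 3]))), 0.05)
  for (s in 1:5) {
    xs <- with_seed_test(10 + s, rgamma(300, shape = 2))
    kd2 <- kde_estimate(xs)
    grid <- seq(min(xs) - 5 * kd2$bw, max(xs) + 5 * kd2$bw,
                length.out = 2048)
    kd2 <- kde_estimate(xs, grid)
    expect_lt(abs(nlomscar:::trapz(kd2$x, kd2$y) - 1), 1e-3)
  }
  ## location equivariance
  kd0 <- kde_estimate(x, grid = seq(-4, 4, 0.01), bw = 0.3)
  kd5 <- kde_estimate(x + 5, grid = seq(1, 9, 0.01), bw = 0.3)
  expect_equal(kd0$y, kd5$y, tolerance = 1e-9)
  expect_error(kde_estimate(rep(3, 10)), "zero-variance")
  expect_error(kde_estimate(c(1, 2)), "at least 5")
})

test_that("KDE overlap is symmetric, bounded and separates shifted data", {
  x <- with_seed_test(2, rnorm(400))
  expect_gt(kde_overlap(x, x), 1 - 1e-6)
  y <- with_seed_test(3, rnorm(400, mean = 10))
  expect_lt(kde_overlap(x, y), 0.01)
  expect_equal(kde_overlap(x, y), kde_overlap(y, x), tolerance = 1e-12)
  ## same-distribution draws overlap highly in nearly all seeds
  hits <- sum(vapply(1:40, function(s) {
    a <- with_seed_test(100 + s, rnorm(500))
    b <- with_seed_test(600 + s, rnorm(500))
    kde_overlap(a, b) > 0.75
  }, TRUE))
  expect_gte(hits, 38)
})

test_that("screening discards batch-shifted features and is threshold-monotone", {
  set.seed(5)
  n <- 120
  tab <- data.frame(
    split = rep(c("train", "test"), each = n),
    stable = rnorm(2 * n),
    shifted = c(rnorm(n), rnorm(n, mean = 10)),   # +10 SD batch shift
    holey = c(rnorm(n), rep(NA, n))
  )
  res <- screen_features(tab, c("stable", "shifted", "holey"), 0.75)
  expect_true(res$kept[res$feature == "stable"])
  expect_false(res$kept[res$feature == "shifted"])
  expect_false(res$kept[res$feature == "holey"])
  expect_match(res$reason[res$feature == "holey"], "missing")
  ## threshold 0 keeps every valid feature; kept set shrinks as the
  ## threshold rises
  r0 <- screen_features(tab, c("stable", "shifted"), 0)
  expect_true(all(r0$kept))
  kept_sets <- lapply(c(0, 0.25, 0.5, 0.75, 0.95), function(th)
    screen_features(tab, c("stable", "shifted"), th)$feature[
      screen_features(tab, c("stable", "shifted"), th)$kept])
  for (i in 2:length(kept_sets))
    expect_true(all(kept_sets[[i]] %in% kept_sets[[i - 1]]))
})

test_that("Kruskal-Wallis handles ties, constants and matches permutation", {
  expect_equal(kruskal_wallis(rep(4, 9), rep(1:3, 3))$p, 1)
  set.seed(6)
  v <- rnorm(15); g <- rep(1:3, each = 5)
  kw <- kruskal_wallis(v, g)
  ## permutation oracle
  perm <- replicate(10000, kruskal.test(v, sample(g))$statistic)
  p_perm <- mean(perm >= kw$H - 1e-12)
  ## Monte-Carlo error plus the chi-square approximation at n = 15
  expect_lt(abs(kw$p - p_perm), 0.05)
  ## two-group case ties to the squared standardized rank-sum statistic
  a <- rnorm(8); b <- rnorm(9) + 0.5
  kw2 <- kruskal_wallis(c(a, b), rep(1:2, c(8, 9)))
  r <- rank(c(a, b))
  w <- sum(r[1:8])
  n1 <- 8; n2 <- 9; n <- 17
  z2 <- (w - n1 * (n + 1) / 2)^2 / (n1 * n2 * (n + 1) / 12)
  expect_equal(kw2$H, z2, tolerance = 1e-9)
})

test_that("rank-sum p-values agree with exact enumeration for small samples", {
  a <- c(1.2, 3.4, 2.2, 5.1)
  b <- c(6.3, 7.7, 4.9, 9.1, 8.2)
  rs <- ranksum(a, b)
  expect_true(rs$exact)
  ## brute force over all C(9, 4) labelings
  pool <- c(a, b)
  combs <- combn(9, 4)
  wobs <- sum(rank(pool)[1:4]) - 4 * 5 / 2
  ws <- apply(combs, 2, function(idx) sum(rank(pool)[idx]) - 4 * 5 / 2)
  mu <- length(b) * length(a) / 2
  p_exact <- mean(abs(ws - mu) >= abs(wobs - mu) - 1e-12)
  expect_equal(rs$p, p_exact, tolerance = 1e-9)
  ## identical and disjoint groups
  expect_gte(ranksum(c(1, 2, 3), c(1, 2, 3))$p, 0.99)
  expect_lt(ranksum(rnorm(10), rnorm(10) + 100)$p, 0.001)
})

test_that("null p-values are approximately uniform", {
  set.seed(9)
  p_kw <- replicate(300, kruskal_wallis(rnorm(30), rep(1:3, each = 10))$p)
  expect_gt(suppressWarnings(ks.test(p_kw, "punif")$p.value), 0.01)
  p_rs <- replicate(300, ranksum(rnorm(12), rnorm(12))$p)
  expect_gt(suppressWarnings(ks.test(p_rs, "punif")$p.value), 0.01)
})

test_that("Pearson matrices match the textbook two-pass formula", {
  set.seed(10)
  rad <- matrix(rnorm(50 * 3), 50, dimnames = list(NULL, c("a", "b", "c")))
  conv <- cbind(x = rad[, "a"], y = -rad[, "a"], z = rnorm(50))
  pm <- pearson_matrix(rad, conv)
  expect_equal(pm["a", "x"], 1, tolerance = 1e-12)
  expect_equal(pm["a", "y"], -1, tolerance = 1e-12)
  r2 <- function(u, v) {
    mu <- sum(u) / length(u); mv <- sum(v) / length(v)
    sum((u - mu) * (v - mv)) /
      sqrt(sum((u - mu)^2) * sum((v - mv)^2))
  }
  for (i in colnames(rad)) for (j in colnames(conv))
    expect_equal(pm[i, j], r2(rad[, i], conv[, j]), tolerance = 1e-12)
  ## zero-variance column flagged as missing
  conv0 <- cbind(conv, w = rep(1, 50))
  pm0 <- pearson_matrix(rad, conv0)
  expect_true(all(is.na(pm0[, "w"])))
})
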