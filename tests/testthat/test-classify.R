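test_that("Monte-Carlo splits are balanced, disjoint and seed-reproducible", {
  y <- rep(c("muscle", "border", "fibrosis"), each = 40)
  plan <- make_mc_splits(y, n_folds = 10, validate_fraction = 0.2, seed = 1)
  expect_equal(plan$per_class, 8)   # floor(0.2 * 120 / 3)
  for (f in plan$folds) {
    expect_equal(length(f$validate), 24)
    expect_equal(as.integer(table(y[f$validate])), c(8L, 8L, 8L))
    expect_equal(sort(c(f$train, f$validate)), 1:120)
    expect_equal(length(intersect(f$train, f$validate)), 0)
  }
  plan2 <- make_mc_splits(y, n_folds = 10, validate_fraction = 0.2, seed = 1)
  expect_identical(plan$folds, plan2$folds)
  plan3 <- make_mc_splits(y, n_folds = 10, validate_fraction = 0.2, seed = 2)
  expect_false(identical(plan$folds[[1]]$validate,
                         plan3$folds[[1]]$validate))
  expect_error(make_mc_splits(rep(c("a", "b"), c(3, 100)), 5, 0.2, 1),
               "infeasible")
})

test_that("imbalance correction interpolates within classes", {
  set.seed(2)
  x <- matrix(rnorm(40 * 3), 40)
  colnames(x) <- c("u", "v", "w")
  y <- rep(c("a", "b"), c(30, 10))
  bal <- balance_training_set(x, y, seed = 3)
  expect_equal(as.integer(table(bal$y)), c(30L, 30L))
  expect_equal(sum(bal$synthetic), 20)
  expect_false(any(bal$synthetic[1:40]))
  ## every synthetic row lies coordinate-wise within the class range
  xb <- bal$x[bal$synthetic, , drop = FALSE]
  rng <- apply(x[31:40, ], 2, range)
  for (j in 1:3) {
    expect_true(all(xb[, j] >= rng[1, j] - 1e-9))
    expect_true(all(xb[, j] <= rng[2, j] + 1e-9))
  }
  ## already balanced input is unchanged
  bal0 <- balance_training_set(x[1:20, ], rep(c("a", "b"), each = 10), 1)
  expect_identical(bal0$x, x[1:20, ])
  expect_false(any(bal0$synthetic))
})

test_that("the ensemble separates a linearly separable problem perfectly", {
  set.seed(4)
  n <- 30
  x <- rbind(cbind(rnorm(n, 0, 0.3), rnorm(n, 0, 0.3)),
             cbind(rnorm(n, 3, 0.3), rnorm(n, 0, 0.3)),
             cbind(rnorm(n, 1.5, 0.3), rnorm(n, 3, 0.3)))
  colnames(x) <- c("f1", "f2")
  y <- rep(c("a", "b", "c"), each = n)
  fit <- train_mc_ensemble(x, y, n_folds = 5, seed = 5)
  expect_true(all(fit$fold_accuracy == 1))
  expect_equal(unname(rowSums(fit$weights)), rep(1, 5), tolerance = 1e-9)
})

test_that("redundant duplicated features are reduced to one", {
  set.seed(6)
  x <- matrix(rnorm(60 * 2), 60)
  x <- cbind(x, x[, 1])   # exact duplicate of column 1
  colnames(x) <- c("a", "b", "adup")
  y <- rep(c("p", "q"), each = 30)
  m <- fit_ensemble(x, y, seed = 7)
  expect_false(all(c("a", "adup") %in% m$keep_names))
  expect_true("a" %in% m$keep_names)   # the first of the pair survives
  expect_equal(unname(m$weights["adup"]), 0)
  expect_equal(sum(m$weights), 1, tolerance = 1e-9)
})

test_that("fold preprocessing never uses validate rows", {
  set.seed(8)
  x <- matrix(rnorm(60 * 3), 60)
  colnames(x) <- c("a", "b", "c")
  y <- rep(c("p", "q"), each = 30)
  tr <- c(1:25, 31:55)
  m1 <- fit_ensemble(x[tr, ], y[tr], seed = 9)
  ## inject an extreme outlier into a validate-only row
  x2 <- x
  x2[56, ] <- 1e6
  m2 <- fit_ensemble(x2[tr, ], y[tr], seed = 9)
  expect_identical(m1$lo, m2$lo)
  expect_identical(m1$rng, m2$rng)
  expect_identical(m1$weights, m2$weights)
})

test_that("majority voting and confusion collapse are exact", {
  ## tally oracle on synthetic vote tables
  votes <- matrix(c("a", "a", "b",
                    "b", "b", "b",
                    "c", "a", "c"), nrow = 3, byrow = TRUE)
  tally <- apply(votes, 1, function(v)
    names(sort(table(v), decreasing = TRUE))[1])
  expect_equal(tally, c("a", "b", "c"))
  ## perfect predictions give an identity-like matrix
  y <- rep(c("muscle", "border", "fibrosis"), each = 5)
  rep1 <- confusion_report(y, y)
  expect_equal(rep1$accuracy, 1)
  expect_true(all(diag(rep1$matrix) == 5))
  expect_equal(rep1$binary_accuracy, 1)
  ## collapse conserves totals and the muscle row
  pred <- c(rep("border", 5), rep("fibrosis", 5), rep("border", 5))
  rep2 <- confusion_report(y, pred)
  expect_equal(sum(rep2$binary_matrix), sum(rep2$matrix))
  expect_equal(unname(rep2$binary_matrix["muscle", ]),
               c(sum(rep2$matrix["muscle", "muscle"]),
                 sum(rep2$matrix["muscle", c("border", "fibrosis")])))
  expect_equal(unname(rep2$binary_sensitivity), 1)
  expect_equal(unname(rep2$binary_specificity), 0)
  expect_error(confusion_report(y, y[1:5]), "mismatch")
})

test_that("label permutation drives accuracy to chance", {
  set.seed(11)
  n <- 25
  x <- rbind(cbind(rnorm(n, 0), rnorm(n, 0)),
             cbind(rnorm(n, 3), rnorm(n, 0)),
             cbind(rnorm(n, 1.5), rnorm(n, 3)))
  colnames(x) <- c("f1", "f2")
  y <- sample(rep(c("a", "b", "c"), each = n))   # permuted labels
  fit <- train_mc_ensemble(x, y, n_folds = 6, seed = 12)
  acc <- mean(fit$fold_accuracy)
  se <- sd(fit$fold_accuracy) / sqrt(6)
  expect_lt(abs(acc - 1 / 3), max(3 * se, 0.15))
})
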