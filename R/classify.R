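## Transparent stand-in for the AutoML protocol: Monte-Carlo train/validate
## splits with class-balanced validation, in-fold preprocessing (range
## normalization, redundancy reduction, univariate selection, imbalance
## correction), a two-layer stacked ensemble of heterogeneous base
## learners, permutation feature weights and confusion-matrix analytics.

default_ml_config <- function() {
  list(
    redundancy_r = 0.95,   # drop one of any feature pair above this |r|
    top_m = 12L,           # univariate (rank-test) feature selection
    knn_k = 5L,
    num_trees = 200L,
    svm_cost = 1,
    inner_folds = 5L,      # out-of-fold stacking for the meta-learner
    perm_reps = 2L         # permutation-importance repetitions
  )
}

#' Monte-Carlo train/validate split plan
#'
#' Each fold selects a class-balanced validate set: an equal number of
#' cases per class totalling approximately `validate_fraction` of all
#' cases (floored to the feasible equal count), leaving the remaining,
#' possibly imbalanced cases as the training split.
#'
#' @param labels class labels.
#' @param n_folds number of Monte-Carlo folds (default 100).
#' @param validate_fraction target validate share (default 0.2).
#' @param seed integer seed.
#' @return object of class `mc_split_plan`: list with `folds` (per fold:
#'   `train`, `validate` row indices), `per_class` and `seed`.
#' @export
make_mc_splits <- function(labels, n_folds = 100L, validate_fraction = 0.2,
                           seed = 1) {
  labels <- as.character(labels)
  cls <- sort(unique(labels))
  k <- length(cls)
  n <- length(labels)
  m <- floor(validate_fraction * n / k)
  if (m < 1) stop2("infeasible split: validate share too small")
  sizes <- table(labels)
  if (any(sizes < m + 1))
    stop2("infeasible split: class '", names(sizes)[which.min(sizes)],
          "' has too few members")
  folds <- with_seed(seed, lapply(seq_len(n_folds), function(f) {
    val <- unlist(lapply(cls, function(cl) {
      ids <- which(labels == cl)
      sample(ids, m)
    }))
    list(train = setdiff(seq_len(n), val), validate = sort(val))
  }))
  structure(list(folds = folds, per_class = m, seed = seed,
                 classes = cls), class = "mc_split_plan")
}

#' Balance a training set by synthetic interpolation
#'
#' Minority classes are upsampled to the majority count with convex
#' interpolation between randomly paired same-class rows (each synthetic
#' row lies on a segment between two originals).  A singleton class is
#' duplicated with small jitter, with a warning.  Already balanced input
#' is returned unchanged.
#'
#' @param x numeric feature matrix.
#' @param y class labels.
#' @param seed integer seed.
#' @return list with `x`, `y` and logical `synthetic` flags.
#' @export
balance_training_set <- function(x, y, seed = 1) {
  y <- as.character(y)
  counts <- table(y)
  maj <- max(counts)
  if (all(counts == maj))
    return(list(x = x, y = y, synthetic = rep(FALSE, nrow(x))))
  with_seed(seed, {
    xs <- list(); ys <- character(0)
    for (cl in names(counts)) {
      need <- maj - counts[[cl]]
      if (need == 0) next
      ids <- which(y == cl)
      if (length(ids) == 1) {
        warning("singleton class '", cl, "': duplicating with jitter")
        sds <- pmax(apply(x, 2, stats::sd), 1e-8)
        new <- matrix(rep(x[ids, ], need), nrow = need, byrow = TRUE) +
          matrix(stats::rnorm(need * ncol(x), 0, 0.01), need) *
          matrix(rep(sds, need), nrow = need, byrow = TRUE)
      } else {
        i1 <- sample(ids, need, replace = TRUE)
        i2 <- vapply(i1, function(i) sample(setdiff(ids, i), 1), 1)
        u <- stats::runif(need)
        new <- x[i1, , drop = FALSE] * (1 - u) + x[i2, , drop = FALSE] * u
      }
      xs[[length(xs) + 1L]] <- new
      ys <- c(ys, rep(cl, need))
    }
    add <- do.call(rbind, xs)
    list(x = rbind(x, add), y = c(y, ys),
         synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, nrow(add))))
  })
}

## internal k-nearest-neighbor class-probability rule (vote fractions over
## the k nearest training rows, Euclidean distance)
knn_fit <- function(x, y, k) list(x = x, y = y, k = min(k, nrow(x)))

knn_prob <- function(model, newx, classes) {
  tr <- model$x
  d2 <- outer(rowSums(newx^2), rep(1, nrow(tr))) +
    outer(rep(1, nrow(newx)), rowSums(tr^2)) - 2 * newx %*% t(tr)
  p <- matrix(0, nrow(newx), length(classes),
              dimnames = list(NULL, classes))
  for (i in seq_len(nrow(newx))) {
    nn <- order(d2[i, ])[seq_len(model$k)]
    tb <- table(factor(model$y[nn], levels = classes))
    p[i, ] <- tb / sum(tb)
  }
  p
}

## rank-test score for univariate feature selection
kw_score <- function(v, y) {
  if (stats::var(v) == 0) return(0)
  out <- tryCatch(stats::kruskal.test(v, factor(y))$statistic,
                  error = function(e) 0)
  if (is.finite(out)) unname(out) else 0
}

base_learner_probs <- function(bases, xz, classes) {
  ps <- e1071_probs(bases$svm, xz, classes)
  pr <- stats::predict(bases$rf, data = as.data.frame(xz))$predictions
  pr <- pr[, classes, drop = FALSE]
  pk <- knn_prob(bases$knn, xz, classes)
  cbind(ps, pr, pk)
}

e1071_probs <- function(svm_model, xz, classes) {
  pred <- stats::predict(svm_model, xz, probability = TRUE)
  pb <- attr(pred, "probabilities")
  pb[, classes, drop = FALSE]
}

#' Fit one stacked-ensemble model
#'
#' In-fold pipeline with no leakage outside the rows given: features are
#' range-normalized to `[0, 1]` from training statistics, one of any pair
#' with `|r|` above the redundancy threshold is dropped, the top-m
#' features by Kruskal-Wallis score are retained, classes are balanced by
#' synthetic interpolation, three heterogeneous base learners (linear-
#' kernel SVM, random forest, k-nearest-neighbor rule) are fitted, and a
#' multinomial meta-learner is trained on out-of-fold base predictions.
#' Per-feature ranking weights are derived by normalized permutation
#' importance of the full stack; dropped features weigh 0.
#'
#' @param x numeric feature matrix (rows = cases), with column names.
#' @param y class labels.
#' @param seed integer seed.
#' @param config list as [default_ml_config()].
#' @return object of class `ensemble_model`.
#' @export
fit_ensemble <- function(x, y, seed = 1, config = default_ml_config()) {
  ## the whole fit runs under a derived seed: some base learners (SVM
  ## probability calibration) draw from the global RNG internally
  with_seed(derive_seed(seed, 3), fit_ensemble_impl(x, y, seed, config))
}

fit_ensemble_impl <- function(x, y, seed, config) {
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2) stop2("degenerate fold: single class")
  x <- as.matrix(x)
  feat_all <- colnames(x)
  ## median imputation from training data
  med <- apply(x, 2, function(v) stats::median(v, na.rm = TRUE))
  med[!is.finite(med)] <- 0
  for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- med[j]
  ## range normalization from training statistics
  lo <- apply(x, 2, min); hi <- apply(x, 2, max)
  rng <- hi - lo
  keep <- rng > 0
  ## redundancy reduction: first of each correlated pair is retained
  xn <- sweep(sweep(x[, keep, drop = FALSE], 2, lo[keep]), 2, rng[keep], "/")
  cm <- suppressWarnings(abs(stats::cor(xn)))
  cm[is.na(cm)] <- 0
  kn <- colnames(xn)
  drop <- logical(length(kn))
  for (j in seq_along(kn)) {
    if (drop[j]) next
    later <- which(cm[j, ] > config$redundancy_r)
    drop[later[later > j]] <- TRUE
  }
  xn <- xn[, !drop, drop = FALSE]
  ## univariate rank-test selection
  scores <- apply(xn, 2, kw_score, y = y)
  sel <- names(sort(scores, decreasing = TRUE))[
    seq_len(min(config$top_m, ncol(xn)))]
  xn <- xn[, sel, drop = FALSE]
  ## imbalance correction (training rows only)
  bal <- balance_training_set(xn, y, derive_seed(seed, 17))
  xb <- bal$x; yb <- factor(bal$y, levels = classes)
  ## syntactic column names for the formula-based learners
  zn <- paste0("f", seq_len(ncol(xb)))
  colnames(xb) <- zn
  fit_bases <- function(xx, yy) {
    list(
      svm = e1071::svm(xx, yy, kernel = "linear", cost = config$svm_cost,
                       probability = TRUE, scale = FALSE),
      rf = ranger::ranger(y = yy, x = as.data.frame(xx),
                          probability = TRUE,
                          num.trees = config$num_trees,
                          seed = derive_seed(seed, 23)),
      knn = knn_fit(xx, as.character(yy), config$knn_k)
    )
  }
  ## out-of-fold base predictions for the meta-learner
  nfold <- min(config$inner_folds, min(table(yb)))
  oof <- matrix(NA_real_, nrow(xb), 3 * length(classes))
  fold_id <- with_seed(derive_seed(seed, 31), {
    unsplit(lapply(split(seq_along(yb), yb),
                   function(ids) sample(rep_len(seq_len(nfold), length(ids)))),
            yb)
  })
  for (f in seq_len(nfold)) {
    tr <- fold_id != f
    if (length(unique(yb[tr])) < length(classes)) next
    bs <- fit_bases(xb[tr, , drop = FALSE], droplevels(yb[tr]))
    oof[!tr, ] <- base_learner_probs(bs, xb[!tr, , drop = FALSE], classes)
  }
  ok <- stats::complete.cases(oof)
  meta_df <- data.frame(.y = yb[ok], oof[ok, , drop = FALSE])
  meta <- nnet::multinom(.y ~ ., meta_df, trace = FALSE, maxit = 300)
  bases <- fit_bases(xb, yb)
  model <- structure(list(
    classes = classes, feature_names = feat_all,
    lo = lo, rng = rng, keep_names = sel, med = med,
    col_map = zn, bases = bases, meta = meta, config = config
  ), class = "ensemble_model")
  ## permutation importance on the (balanced) training rows
  base_acc <- mean(predict_ensemble(model, denormalize(model, xb)) ==
                     as.character(yb))
  imp <- numeric(length(sel))
  with_seed(derive_seed(seed, 41), {
    for (j in seq_along(sel)) {
      accs <- numeric(config$perm_reps)
      for (r in seq_len(config$perm_reps)) {
        xp <- xb
        xp[, j] <- sample(xp[, j])
        accs[r] <- mean(predict_ensemble(model, denormalize(model, xp)) ==
                          as.character(yb))
      }
      imp[j] <- base_acc - mean(accs)
    }
  })
  imp <- pmax(imp, 0)
  w <- stats::setNames(rep(0, length(feat_all)), feat_all)
  w[sel] <- if (sum(imp) > 0) imp / sum(imp) else rep(1 / length(sel),
                                                      length(sel))
  model$weights <- w
  model
}

## invert the model's range normalization (utility for importance eval)
denormalize <- function(model, xn) {
  out <- xn
  colnames(out) <- model$keep_names
  for (j in seq_along(model$keep_names)) {
    f <- model$keep_names[j]
    out[, j] <- xn[, j] * model$rng[f] + model$lo[f]
  }
  out
}

#' Predict classes with a fitted ensemble
#'
#' @param model an `ensemble_model`.
#' @param newx feature matrix with (at least) the model's feature columns.
#' @param type `"class"` or `"prob"`.
#' @return class labels, or a probability matrix.
#' @export
predict_ensemble <- function(model, newx, type = c("class", "prob")) {
  type <- match.arg(type)
  newx <- as.matrix(newx)
  xs <- newx[, model$keep_names, drop = FALSE]
  for (j in seq_len(ncol(xs))) {
    f <- model$keep_names[j]
    v <- xs[, j]
    v[is.na(v)] <- model$med[f]
    xs[, j] <- (v - model$lo[f]) / model$rng[f]
  }
  colnames(xs) <- model$col_map
  z <- base_learner_probs(model$bases, xs, model$classes)
  zdf <- as.data.frame(z)
  names(zdf) <- paste0("X", seq_len(ncol(z)))
  pp <- stats::predict(model$meta, zdf, type = "probs")
  if (is.null(dim(pp))) {   # two-class multinom returns a vector
    pp <- cbind(1 - pp, pp)
    colnames(pp) <- model$meta$lev
  }
  pp <- pp[, model$classes, drop = FALSE]
  if (type == "prob") return(pp)
  model$classes[max.col(pp)]
}

#' Train the Monte-Carlo ensemble
#'
#' Fits one stacked ensemble per Monte-Carlo fold and evaluates it on the
#' fold's balanced validate split.
#'
#' @param x feature matrix.
#' @param y class labels.
#' @param n_folds,validate_fraction,seed passed to [make_mc_splits()].
#' @param config as [default_ml_config()].
#' @return list with `models`, `fold_accuracy` (per-fold validate
#'   accuracy), `weights` (folds x features matrix) and the split plan.
#' @export
train_mc_ensemble <- function(x, y, n_folds = 100L, validate_fraction = 0.2,
                              seed = 1, config = default_ml_config()) {
  x <- as.matrix(x)
  plan <- make_mc_splits(y, n_folds, validate_fraction, seed)
  models <- vector("list", n_folds)
  acc <- rep(NA_real_, n_folds)
  wts <- matrix(NA_real_, n_folds, ncol(x),
                dimnames = list(NULL, colnames(x)))
  for (f in seq_len(n_folds)) {
    tr <- plan$folds[[f]]$train
    va <- plan$folds[[f]]$validate
    if (length(unique(y[tr])) < 2) next
    m <- fit_ensemble(x[tr, , drop = FALSE], y[tr],
                      seed = derive_seed(seed, 1000 + f), config = config)
    models[[f]] <- m
    acc[f] <- mean(predict_ensemble(m, x[va, , drop = FALSE]) == y[va])
    wts[f, ] <- m$weights
  }
  list(models = models, fold_accuracy = acc, weights = wts, plan = plan)
}

#' Majority-vote prediction over Monte-Carlo fold models
#'
#' @param models list of `ensemble_model`s (NULL entries are skipped).
#' @param newx feature matrix.
#' @return predicted class labels.
#' @export
predict_mc <- function(models, newx) {
  models <- Filter(Negate(is.null), models)
  if (length(models) == 0) stop2("no fitted fold models")
  votes <- vapply(models, function(m) predict_ensemble(m, newx),
                  character(nrow(as.matrix(newx))))
  votes <- matrix(votes, nrow = nrow(as.matrix(newx)))
  apply(votes, 1, function(v) names(sort(table(v), decreasing = TRUE))[1])
}

#' Confusion-matrix report with pathological collapse
#'
#' Builds the k-class confusion matrix (rows = truth), overall accuracy
#' and per-class sensitivity, and collapses the pathological classes
#' (border and fibrosis by default) into one to report binary accuracy,
#' sensitivity for pathological tissue and specificity for healthy
#' muscle.
#'
#' @param truth true class labels.
#' @param pred predicted class labels.
#' @param pathological classes collapsed into the pathological label.
#' @return list with `matrix`, `accuracy`, `sensitivity`,
#'   `binary_matrix`, `binary_accuracy`, `binary_sensitivity`,
#'   `binary_specificity`.
#' @export
confusion_report <- function(truth, pred,
                             pathological = c("border", "fibrosis")) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (length(truth) != length(pred)) stop2("label length mismatch")
  cls <- sort(unique(c(truth, pred)))
  cm <- table(factor(truth, cls), factor(pred, cls))
  acc <- sum(diag(cm)) / sum(cm)
  sens <- diag(cm) / rowSums(cm)
  collapse <- function(v) ifelse(v %in% pathological, "pathological", v)
  bt <- collapse(truth); bp <- collapse(pred)
  bcls <- sort(unique(c(bt, bp)))
  bm <- table(factor(bt, bcls), factor(bp, bcls))
  bacc <- sum(diag(bm)) / sum(bm)
  bsens <- if ("pathological" %in% rownames(bm))
    bm["pathological", "pathological"] / sum(bm["pathological", ]) else NA
  healthy <- setdiff(bcls, "pathological")
  bspec <- if (length(healthy) == 1)
    bm[healthy, healthy] / sum(bm[healthy, ]) else NA
  list(matrix = cm, accuracy = acc, sensitivity = sens,
       binary_matrix = bm, binary_accuracy = bacc,
       binary_sensitivity = bsens, binary_specificity = bspec)
}
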