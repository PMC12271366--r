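## Train/test feature harmonization by kernel-density overlap, group
## significance tests and the radiomics-vs-conventional correlation matrix.

kde_bandwidth <- function(x) {
  bw <- tryCatch(stats::bw.SJ(x), error = function(e) NA_real_)
  if (!is.finite(bw) || bw <= 0) bw <- stats::bw.nrd0(x)
  if (!is.finite(bw) || bw <= 0) stop2("bandwidth selection failed")
  bw
}

#' Gaussian kernel density estimate on a grid
#'
#' Exact Gaussian KDE with automatic bandwidth (Sheather-Jones
#' solve-the-equation selection, falling back to Silverman's rule when the
#' SJ equation has no solution), evaluated at the requested grid points.
#'
#' @param samples numeric vector (>= 5 finite values, nonzero variance).
#' @param grid evaluation points; defaults to 512 points spanning the
#'   sample range padded by 3 bandwidths.
#' @param bw bandwidth; `NULL` for automatic selection.
#' @return list with `x` (grid), `y` (density) and `bw`.
#' @export
kde_estimate <- function(samples, grid = NULL, bw = NULL) {
  x <- samples[is.finite(samples)]
  if (length(x) < 5) stop2("need at least 5 finite samples")
  if (stats::var(x) == 0) stop2("zero-variance sample")
  if (is.null(bw)) bw <- kde_bandwidth(x)
  if (is.null(grid))
    grid <- seq(min(x) - 3 * bw, max(x) + 3 * bw, length.out = 512)
  y <- vapply(grid, function(g) mean(stats::dnorm((g - x) / bw)) / bw, 1)
  list(x = grid, y = y, bw = bw)
}

#' Kernel density overlap of two samples
#'
#' The integral of the pointwise minimum of the two kernel density
#' estimates, evaluated by trapezoid quadrature on a 2048-point grid
#' spanning both samples' ranges padded by 5 bandwidths (wide enough that
#' truncated kernel tails cost less than 1e-6 of mass).  Symmetric in its
#' arguments and bounded in `[0, 1]`; a value near 1 means the feature is
#' distributed alike in both sets.
#'
#' @param train_samples,test_samples numeric vectors.
#' @param n_grid grid resolution.
#' @return overlap in `[0, 1]`.
#' @export
kde_overlap <- function(train_samples, test_samples, n_grid = 2048) {
  a <- train_samples[is.finite(train_samples)]
  b <- test_samples[is.finite(test_samples)]
  bwa <- kde_bandwidth_checked(a)
  bwb <- kde_bandwidth_checked(b)
  pad <- 5 * max(bwa, bwb)
  grid <- seq(min(a, b) - pad, max(a, b) + pad, length.out = n_grid)
  fa <- kde_estimate(a, grid, bwa)$y
  fb <- kde_estimate(b, grid, bwb)$y
  min(max(trapz(grid, pmin(fa, fb)), 0), 1)
}

kde_bandwidth_checked <- function(x) {
  if (length(x) < 5) stop2("need at least 5 finite samples")
  if (stats::var(x) == 0) stop2("zero-variance sample")
  kde_bandwidth(x)
}

#' Screen features by train/test KDE overlap
#'
#' Features whose train and test distributions overlap by less than
#' `threshold` are discarded as non-quantitative (batch-affected); the
#' rest are kept.  Features with more than `max_na_frac` missing values
#' are dropped with a logged reason.
#'
#' @param table data frame with a `split` column (`"train"`/`"test"`) and
#'   numeric feature columns.
#' @param features character vector of feature column names to screen.
#' @param threshold overlap threshold (default 0.75).
#' @param max_na_frac maximal tolerated fraction of missing values.
#' @return data frame with columns `feature`, `overlap`, `kept`, `reason`.
#' @export
screen_features <- function(table, features, threshold = 0.75,
                            max_na_frac = 0.2) {
  stopifnot(all(c("split") %in% names(table)))
  if (!all(c("train", "test") %in% table$split))
    stop2("table must contain both train and test splits")
  res <- lapply(features, function(f) {
    v <- table[[f]]
    if (mean(is.na(v)) > max_na_frac)
      return(data.frame(feature = f, overlap = NA_real_, kept = FALSE,
                        reason = "too many missing values"))
    ov <- tryCatch(
      kde_overlap(v[table$split == "train"], v[table$split == "test"]),
      error = function(e) NA_real_)
    if (is.na(ov))
      return(data.frame(feature = f, overlap = NA_real_, kept = FALSE,
                        reason = "degenerate distribution"))
    data.frame(feature = f, overlap = ov, kept = ov >= threshold,
               reason = "")
  })
  do.call(rbind, res)
}

#' Kruskal-Wallis rank test across tissue classes
#'
#' Tie-corrected H statistic with a chi-square reference distribution;
#' completely tied data yield `H = 0`, `p = 1`.
#'
#' @param values numeric vector.
#' @param groups group labels (>= 2 groups).
#' @param alpha significance level for the `significant` flag.
#' @return list with `H`, `df`, `p` and `significant`.
#' @export
kruskal_wallis <- function(values, groups, alpha = 0.05) {
  ok <- is.finite(values)
  values <- values[ok]; groups <- factor(groups[ok])
  if (nlevels(groups) < 2) stop2("need at least 2 groups")
  if (length(values) < 3) stop2("need at least 3 observations")
  if (stats::var(values) == 0) {
    return(list(H = 0, df = nlevels(groups) - 1, p = 1, significant = FALSE))
  }
  kt <- stats::kruskal.test(values, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value, significant = kt$p.value < alpha)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Two-sided Wilcoxon-Mann-Whitney test; the null distribution is
#' enumerated exactly for small untied samples (`n_a + n_b <= 12`) and
#' approximated normally with tie correction otherwise.
#'
#' @param group_a,group_b numeric vectors.
#' @param alpha significance level.
#' @return list with `W`, `p`, `exact` and `significant`.
#' @export
ranksum <- function(group_a, group_b, alpha = 0.05) {
  a <- group_a[is.finite(group_a)]; b <- group_b[is.finite(group_b)]
  if (length(a) == 0 || length(b) == 0) stop2("both groups must be non-empty")
  ties <- any(duplicated(c(a, b)))
  use_exact <- (length(a) + length(b) <= 12) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = !use_exact))
  list(W = unname(wt$statistic), p = wt$p.value, exact = use_exact,
       significant = wt$p.value < alpha)
}

#' Pearson correlation matrix between two feature blocks
#'
#' Pairwise-complete Pearson coefficients between radiomic and
#' conventional feature columns; zero-variance columns are flagged with a
#' row/column of missing values.
#'
#' @param rad data frame (or matrix) of radiomic feature columns.
#' @param conv data frame (or matrix) of conventional feature columns.
#' @return matrix of r values, rows = radiomic features, columns =
#'   conventional features.
#' @export
pearson_matrix <- function(rad, conv) {
  rad <- as.matrix(rad); conv <- as.matrix(conv)
  if (nrow(rad) != nrow(conv)) stop2("row mismatch between blocks")
  out <- suppressWarnings(stats::cor(rad, conv, use = "pairwise.complete.obs",
                                     method = "pearson"))
  out
}
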