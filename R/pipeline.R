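## End-to-end orchestration: simulate -> segment -> conventional features
## -> radiomics -> KDE screening -> statistics -> Monte-Carlo ensemble.

#' Default pipeline configuration
#'
#' One list holding every tunable stage parameter: phenotype presets,
#' dataset layout (classes x ROIs x frames, with ROIs alternating between
#' two pseudo-subjects), frame geometry, preprocessing parameters
#' (Frangi scales, entropy order, binning), fiber-tracer settings, the
#' KDE screening threshold, and the machine-learning configuration.  The
#' benchmark layout is 4 ROIs per class (two per pseudo-subject) with 15
#' frames per ROI at 256 px frames.
#'
#' @param ... named overrides of the defaults.
#' @return configuration list.
#' @export
default_config <- function(...) {
  cfg <- list(
    presets = phenotype_presets(),
    n_per_class_per_roi = 15L,
    n_rois = 4L,
    size_px = 256L,
    pixel_size_um = 508 / 512,
    roi_jitter_sd = 0.12,
    frangi_scales = c(1.8, 4.9, 8),
    frangi_beta = 0.5,
    frangi_c_mode = "auto",
    scale_is_diameter = FALSE,
    renyi_order = 1,
    bin_factor = 4L,
    glcm_distance = 1L,
    peak_radius = 3,
    fiber_min_length_px = 15,
    fiber_merge_angle_deg = 30,
    screen_threshold = 0.75,
    radiomics_enabled = TRUE,
    n_folds = 20L,
    validate_fraction = 0.2,
    ml = default_ml_config()
  )
  over <- list(...)
  cfg[names(over)] <- over
  cfg
}

config_hash <- function(config) {
  tf <- tempfile(fileext = ".json")
  on.exit(unlink(tf))
  writeLines(jsonlite::toJSON(config, auto_unbox = TRUE, digits = 12,
                              force = TRUE), tf)
  unname(tools::md5sum(tf))
}

#' Extract the full feature table of a dataset
#'
#' Runs the segmentation pipelines per ROI stack (thresholds are stack
#' level, as acquired), traces fibers, computes the 16 conventional
#' features per frame and, when enabled, the radiomic panel of both
#' modalities on the dataset-wide preprocessed images.
#'
#' @param dataset output of [generate_dataset()] (or an equivalent list
#'   with `frames` and `manifest`).
#' @param config a [default_config()].
#' @param verbose print per-ROI progress.
#' @return data frame: manifest columns, then conventional features, then
#'   radiomic features (columns named `"<MOD>::<Family>::<name>"`).
#' @export
extract_features <- function(dataset, config = default_config(),
                             verbose = FALSE) {
  man <- dataset$manifest
  frames <- dataset$frames
  n <- nrow(man)
  conv <- matrix(NA_real_, n, 16,
                 dimnames = list(NULL, conventional_feature_names()))
  for (roi in unique(man$roi)) {
    ids <- which(man$roi == roi)
    if (verbose) message("segmenting ", roi, " (", length(ids), " frames)")
    shg_stack <- lapply(frames[ids], `[[`, "shg")
    tpef_stack <- lapply(frames[ids], `[[`, "tpef")
    seg_s <- segment_collagen_pipeline(
      shg_stack, scales_px = config$frangi_scales, beta = config$frangi_beta,
      c_mode = config$frangi_c_mode,
      scale_is_diameter = config$scale_is_diameter,
      renyi_order = config$renyi_order)
    seg_t <- segment_tpef_pipeline(tpef_stack,
                                   renyi_order = config$renyi_order)
    for (k in seq_along(ids)) {
      i <- ids[k]
      fibers <- trace_fibers(seg_s$binary[[k]], seg_s$enhanced[[k]],
                             pixel_size_um = config$pixel_size_um,
                             min_length_px = config$fiber_min_length_px,
                             merge_angle_deg = config$fiber_merge_angle_deg)
      conv[i, ] <- conventional_feature_vector(
        frames[[i]]$shg, frames[[i]]$tpef,
        seg_s$binary[[k]], seg_t$binary[[k]], fibers)
    }
  }
  out <- cbind(man, as.data.frame(conv, check.names = FALSE))
  if (isTRUE(config$radiomics_enabled)) {
    rp <- radiomics_preprocess(frames, config$bin_factor)
    rad <- NULL
    for (i in seq_len(n)) {
      if (is.null(rp$frames[[i]])) next
      v <- c(compute_feature_panel(rp$frames[[i]]$shg,
                                   config$glcm_distance, config$peak_radius),
             compute_feature_panel(rp$frames[[i]]$tpef,
                                   config$glcm_distance, config$peak_radius))
      if (is.null(rad))
        rad <- matrix(NA_real_, n, length(v),
                      dimnames = list(NULL, names(v)))
      rad[i, ] <- v
    }
    if (!is.null(rad))
      out <- cbind(out, as.data.frame(rad, check.names = FALSE))
  }
  out
}

#' Names of the radiomic feature columns of a feature table
#' @param table a feature table from [extract_features()].
#' @return character vector.
#' @export
radiomic_feature_names <- function(table) {
  grep("::", names(table), value = TRUE, fixed = TRUE)
}

#' Run the full analysis pipeline
#'
#' Simulates the labeled dataset, extracts conventional and radiomic
#' features, splits by pseudo-subject (subject 1 trains, subject 2
#' tests), screens radiomic features by train/test KDE overlap, computes
#' the conventional-feature significance tests and the radiomics-vs-
#' conventional Pearson matrix, trains the Monte-Carlo stacked ensemble
#' on the retained radiomic features and evaluates it on the held-out
#' subject.  All artifacts are written under `out_dir` tagged with the
#' configuration hash; identical config and seed reproduce identical
#' artifacts.
#'
#' @param config a [default_config()].
#' @param seed integer master seed.
#' @param out_dir output directory (created if missing); `NULL` skips
#'   writing.
#' @param verbose print stage progress.
#' @return list with `features`, `screen`, `stats`, `pearson`, `fit`,
#'   `cv` (per-fold accuracies), `test_report`, `config_hash`.
#' @export
run_pipeline <- function(config = default_config(), seed = 1,
                         out_dir = NULL, verbose = FALSE) {
  hash <- config_hash(config)
  say <- function(...) if (verbose) message(...)
  say("simulating dataset")
  ds <- generate_dataset(config$presets, config$n_per_class_per_roi,
                         config$n_rois, seed, config$size_px,
                         config$pixel_size_um, config$roi_jitter_sd)
  say("extracting features")
  tab <- extract_features(ds, config, verbose = verbose)
  tab$split <- ifelse(tab$subject == "subject1", "train", "test")
  rad_cols <- radiomic_feature_names(tab)
  conv_cols <- conventional_feature_names()
  ## screening (radiomic features only; needs both splits)
  screen <- NULL
  kept <- character(0)
  if (length(rad_cols) > 0 && all(c("train", "test") %in% tab$split)) {
    say("screening radiomic features")
    screen <- screen_features(tab, rad_cols, config$screen_threshold)
    kept <- screen$feature[screen$kept]
  } else if (length(rad_cols) > 0) {
    say("single-subject dataset: skipping train/test screening")
    kept <- rad_cols
  }
  ## conventional-feature statistics
  say("testing conventional features")
  stats_rows <- lapply(conv_cols, function(f) {
    v <- tab[[f]]
    kw <- tryCatch(kruskal_wallis(v, tab$class),
                   error = function(e) list(H = NA, p = NA,
                                            significant = NA))
    rs <- tryCatch(
      ranksum(v[tab$class == "muscle"], v[tab$class != "muscle"]),
      error = function(e) list(W = NA, p = NA, significant = NA))
    data.frame(feature = f, kw_H = kw$H, kw_p = kw$p,
               kw_significant = kw$significant,
               binary_W = rs$W, binary_p = rs$p,
               binary_significant = rs$significant)
  })
  stats_df <- do.call(rbind, stats_rows)
  ## correlation of (kept) radiomics against conventional features
  pearson <- NULL
  if (length(kept) > 0) {
    say("correlating radiomic and conventional features")
    pearson <- pearson_matrix(tab[, kept, drop = FALSE],
                              tab[, conv_cols, drop = FALSE])
  }
  ## classification on the training subject, tested on the held-out one
  fit <- NULL; test_report <- NULL; cv <- NULL
  ml_features <- if (length(kept) > 0) kept else conv_cols
  tr <- tab$split == "train"
  say("training Monte-Carlo ensemble (", sum(tr), " train frames, ",
      length(ml_features), " features)")
  fit <- tryCatch(
    train_mc_ensemble(as.matrix(tab[tr, ml_features, drop = FALSE]),
                      tab$class[tr], n_folds = config$n_folds,
                      validate_fraction = config$validate_fraction,
                      seed = derive_seed(seed, 77), config = config$ml),
    error = function(e) {
      say("training skipped: ", conditionMessage(e))
      NULL
    })
  if (!is.null(fit)) {
    cv <- fit$fold_accuracy
    if (any(!tr)) {
      pred <- predict_mc(fit$models,
                         as.matrix(tab[!tr, ml_features, drop = FALSE]))
      test_report <- confusion_report(tab$class[!tr], pred)
    }
  }
  res <- list(features = tab, screen = screen, stats = stats_df,
              pearson = pearson, fit = fit, cv = cv,
              test_report = test_report, config_hash = hash)
  if (!is.null(out_dir)) write_pipeline_artifacts(res, config, out_dir)
  res
}

write_pipeline_artifacts <- function(res, config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  stamp <- function(df) {
    attr(df, "config_hash") <- res$config_hash
    df
  }
  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    con <- file(p, "w")
    writeLines(paste0("# config_hash=", res$config_hash), con)
    utils::write.csv(df, con, row.names = FALSE)
    close(con)
  }
  wcsv(res$features, "features.csv")
  if (!is.null(res$screen)) wcsv(res$screen, "screen.csv")
  wcsv(res$stats, "conventional_stats.csv")
  if (!is.null(res$pearson))
    wcsv(data.frame(feature = rownames(res$pearson), res$pearson,
                    check.names = FALSE), "pearson.csv")
  rep <- list(config_hash = res$config_hash)
  if (!is.null(res$fit)) {
    rep$cv_accuracy_mean <- mean(res$cv, na.rm = TRUE)
    rep$cv_accuracy_sd <- stats::sd(res$cv, na.rm = TRUE)
    rep$fold_accuracy <- res$cv
    rep$mean_feature_weights <-
      as.list(colMeans(res$fit$weights, na.rm = TRUE))
  }
  if (!is.null(res$test_report)) {
    rep$test <- list(
      accuracy = res$test_report$accuracy,
      sensitivity = as.list(res$test_report$sensitivity),
      binary_accuracy = res$test_report$binary_accuracy,
      binary_sensitivity = res$test_report$binary_sensitivity,
      binary_specificity = res$test_report$binary_specificity,
      confusion = as.data.frame(res$test_report$matrix)
    )
  }
  jsonlite::write_json(rep, file.path(out_dir, "ml_report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  jsonlite::write_json(config, file.path(out_dir, "config.json"),
                       auto_unbox = TRUE, digits = 12, force = TRUE,
                       pretty = TRUE)
  invisible(out_dir)
}
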