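#!/usr/bin/env Rscript
## Monte-Carlo stacked-ensemble classification of tissue class from the
## screened radiomic features: subject 1 trains (with internal 20-fold
## Monte-Carlo validation), subject 2 is the independent test set.
## Writes ml_report.json and the test confusion matrix.
##
## Usage: Rscript analysis/04_classify.R [--seed N]

suppressMessages(library(nlomscar))

args <- commandArgs(trailingOnly = TRUE)
seed <- if ("--seed" %in% args) as.integer(args[which(args == "--seed") + 1]) else 1L

out_dir <- "results/analysis"
tab <- read.csv(file.path(out_dir, "features.csv"), check.names = FALSE)
tab$split <- ifelse(tab$subject == "subject1", "train", "test")
scr <- read.csv(file.path(out_dir, "screen.csv"))
kept <- scr$feature[scr$kept]

cfg <- default_config()
tr <- tab$split == "train"
message("training ", cfg$n_folds, "-fold Monte-Carlo ensemble on ",
        sum(tr), " frames / ", length(kept), " features")
fit <- train_mc_ensemble(as.matrix(tab[tr, kept, drop = FALSE]),
                         tab$class[tr], n_folds = cfg$n_folds,
                         validate_fraction = cfg$validate_fraction,
                         seed = seed)
message("cross-validation accuracy: ",
        round(100 * mean(fit$fold_accuracy, na.rm = TRUE), 1), "% +/- ",
        round(100 * sd(fit$fold_accuracy, na.rm = TRUE), 1), "%")

pred <- predict_mc(fit$models, as.matrix(tab[!tr, kept, drop = FALSE]))
rep <- confusion_report(tab$class[!tr], pred)
message("held-out subject: 3-class accuracy ",
        round(100 * rep$accuracy, 1), "%, binary accuracy ",
        round(100 * rep$binary_accuracy, 1), "%")

w <- colMeans(fit$weights, na.rm = TRUE)
top <- sort(w, decreasing = TRUE)[1:10]
message("top feature weights:\n",
        paste(sprintf("  %-45s %5.1f%%", names(top), 100 * top),
              collapse = "\n"))

jsonlite::write_json(list(
  seed = seed,
  cv_accuracy_mean = mean(fit$fold_accuracy, na.rm = TRUE),
  cv_accuracy_sd = sd(fit$fold_accuracy, na.rm = TRUE),
  test_accuracy = rep$accuracy,
  test_binary_accuracy = rep$binary_accuracy,
  test_sensitivity = as.list(rep$sensitivity),
  confusion = as.data.frame.matrix(rep$matrix),
  mean_feature_weights = as.list(w)
), file.path(out_dir, "ml_report.json"), auto_unbox = TRUE, digits = 10,
  pretty = TRUE)
write.csv(as.data.frame.matrix(rep$matrix),
          file.path(out_dir, "test_confusion.csv"))
message("wrote ", file.path(out_dir, "ml_report.json"))
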