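#!/usr/bin/env Rscript
## Simulate the labeled two-channel dataset: three tissue classes (muscle,
## border, fibrosis), four ROIs per class split over two pseudo-subjects,
## 15 frames per ROI.  Stacks are written as interleaved two-channel
## 16-bit multi-page TIFFs (one per ROI) plus a manifest CSV.
##
## Usage: Rscript analysis/01_simulate.R [--seed N]

suppressMessages(library(nlomscar))

args <- commandArgs(trailingOnly = TRUE)
seed <- if ("--seed" %in% args) as.integer(args[which(args == "--seed") + 1]) else 1L

cfg <- default_config()
data_dir <- "scratch/analysis/data"
dir.create(data_dir, recursive = TRUE, showWarnings = FALSE)

message("simulating ", 3 * cfg$n_rois * cfg$n_per_class_per_roi,
        " frames at ", cfg$size_px, " px (seed ", seed, ")")
ds <- generate_dataset(cfg$presets, cfg$n_per_class_per_roi, cfg$n_rois,
                       seed, cfg$size_px, cfg$pixel_size_um,
                       cfg$roi_jitter_sd)

for (roi in unique(ds$manifest$roi)) {
  ids <- which(ds$manifest$roi == roi)
  stack <- two_channel_stack(ds$frames[ids], 16L, cfg$pixel_size_um,
                             provenance = paste0("synthetic:", roi))
  write_stack(stack, file.path(data_dir, paste0(roi, ".tif")))
}
write.csv(ds$manifest, file.path(data_dir, "manifest.csv"), row.names = FALSE)

cls <- table(ds$manifest$class)
message("wrote ", length(unique(ds$manifest$roi)), " ROI stacks under ",
        data_dir, "; class counts: ",
        paste(names(cls), cls, sep = "=", collapse = ", "))
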