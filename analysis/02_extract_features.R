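#!/usr/bin/env Rscript
## Read the simulated ROI stacks back from TIFF and extract, per frame,
## the 16 conventional features (collagen amount, fiber morphology,
## directionality) and the radiomic panel of both modalities.  Writes
## results/analysis/features.csv.
##
## Usage: Rscript analysis/02_extract_features.R

suppressMessages(library(nlomscar))

data_dir <- "scratch/analysis/data"
out_dir <- "results/analysis"
dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

man <- read.csv(file.path(data_dir, "manifest.csv"))
frames <- vector("list", nrow(man))
for (roi in unique(man$roi)) {
  st <- read_stack(file.path(data_dir, paste0(roi, ".tif")))
  frames[which(man$roi == roi)] <- st$frames
}

cfg <- default_config()
t0 <- Sys.time()
tab <- extract_features(list(frames = frames, manifest = man), cfg,
                        verbose = TRUE)
message("extracted ", length(radiomic_feature_names(tab)),
        " radiomic + 16 conventional features for ", nrow(tab),
        " frames in ",
        round(as.numeric(difftime(Sys.time(), t0, units = "mins")), 1),
        " min")

write.csv(tab, file.path(out_dir, "features.csv"), row.names = FALSE)
message("wrote ", file.path(out_dir, "features.csv"))
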