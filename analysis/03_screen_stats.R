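#!/usr/bin/env Rscript
## Harmonization and statistics: screen radiomic features by train/test
## kernel-density overlap at 0.75, run the three-class Kruskal-Wallis and
## binary (muscle vs pathological) rank-sum tests on the conventional
## features, and correlate retained radiomics against the conventional
## features.  Writes screen.csv, conventional_stats.csv, pearson.csv.
##
## Usage: Rscript analysis/03_screen_stats.R

suppressMessages(library(nlomscar))

out_dir <- "results/analysis"
tab <- read.csv(file.path(out_dir, "features.csv"), check.names = FALSE)
tab$split <- ifelse(tab$subject == "subject1", "train", "test")

rad <- radiomic_feature_names(tab)
scr <- screen_features(tab, rad, threshold = 0.75)
write.csv(scr, file.path(out_dir, "screen.csv"), row.names = FALSE)
message(sum(scr$kept), " of ", nrow(scr),
        " radiomic features kept at KDE overlap >= 0.75 (",
        sum(grepl("^SHG", scr$feature[scr$kept])), " SHG, ",
        sum(grepl("^TPEF", scr$feature[scr$kept])), " TPEF)")

conv <- conventional_feature_names()
rows <- lapply(conv, function(f) {
  v <- tab[[f]]
  kw <- tryCatch(kruskal_wallis(v, tab$class),
                 error = function(e) list(H = NA, p = NA, significant = NA))
  rs <- tryCatch(ranksum(v[tab$class == "muscle"], v[tab$class != "muscle"]),
                 error = function(e) list(W = NA, p = NA, significant = NA))
  data.frame(feature = f, kw_H = kw$H, kw_p = kw$p,
             kw_significant = kw$significant, binary_p = rs$p,
             binary_significant = rs$significant)
})
stats_df <- do.call(rbind, rows)
write.csv(stats_df, file.path(out_dir, "conventional_stats.csv"),
          row.names = FALSE)
message(sum(stats_df$kw_significant, na.rm = TRUE),
        " of 16 conventional features significant in the 3-class test, ",
        sum(stats_df$binary_significant, na.rm = TRUE),
        " in the binary test (p < 0.05)")

kept <- scr$feature[scr$kept]
if (length(kept) > 0) {
  pm <- pearson_matrix(tab[, kept, drop = FALSE], tab[, conv, drop = FALSE])
  write.csv(data.frame(feature = rownames(pm), pm, check.names = FALSE),
            file.path(out_dir, "pearson.csv"), row.names = FALSE)
  message("max |r| between radiomic and conventional features: ",
          round(max(abs(pm), na.rm = TRUE), 2))
}
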