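#!/usr/bin/env Rscript
# Extract the 214-feature bank (107 per modality) from every case for the
# three ROI variants: the segmented mask as-is, and with 0.25 cm and
# 0.5 cm boundary shells eroded per slice.
#
# Requires 02_segment.R.  Outputs: results/features_{variant}.csv.

suppressMessages(library(pitradiomics))

rec <- read.csv("results/cohort.csv")
cases <- lapply(seq_len(nrow(rec)), function(i) {
  id <- rec$case_id[i]
  list(t1ce = read_volume(file.path("scratch/volumes",
                                    paste0(id, "_t1ce.nii.gz")), "T1CE") |>
         resample_isotropic(),
       t2 = read_volume(file.path("scratch/volumes",
                                  paste0(id, "_t2.nii.gz")), "T2") |>
         resample_isotropic(),
       mask = read_mask(file.path("scratch/masks",
                                  paste0(id, "_mask.nii.gz"))),
       record = rec[i, ])
})

for (depth in c(0, 0.25, 0.5)) {
  vn <- if (depth == 0) "original" else sprintf("eroded_%03d", depth * 100)
  feats <- extract_cohort_features(cases, erosion_cm = depth, n_bins = 32)
  write.csv(feats, sprintf("results/features_%s.csv", vn), row.names = FALSE)
  cat(sprintf("%s: %d cases x %d features\n", vn, nrow(feats),
              ncol(feats) - 1))
}
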