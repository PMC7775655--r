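#!/usr/bin/env Rscript
# Sequential forward feature selection under the Gaussian-kernel SVM
# cross-validation objective (3-feature model), out-of-fold SVM scores,
# ROC with Youden-optimal cutoff, and the per-variant performance table.
#
# Requires 03_features.R.  Outputs: results/performance_by_variant.csv,
# results/scores.csv, results/selected_features.csv.

suppressMessages(library(pitradiomics))

rec <- read.csv("results/cohort.csv")
y <- rec$pr

perf <- NULL; selrows <- NULL; score_tab <- NULL
for (vn in c("original", "eroded_025", "eroded_050")) {
  f <- sprintf("results/features_%s.csv", vn)
  if (!file.exists(f)) next
  feats <- read.csv(f, check.names = FALSE)
  X <- as.matrix(feats[, setdiff(names(feats), "case_id")])
  yv <- y[match(feats$case_id, rec$case_id)]
  sel <- sequential_select(X, yv, tol = 1e-6, repeats = 3,
                           max_features = 3, seed = 1)
  sc <- pitradiomics:::cv_scores(X, yv, sel$selected, folds = 10, seed = 99)
  roc <- roc_analysis(sc, yv)
  cf <- confusion(sc, yv, roc$cutoff)
  cat(sprintf("%s: selected %s | AUC %.2f, cutoff %.3f, accuracy %.0f%%\n",
              vn, paste(sel$selected, collapse = ", "), roc$auc,
              roc$cutoff, 100 * cf$accuracy))
  perf <- rbind(perf, data.frame(variant = vn, tp = cf$tp, tn = cf$tn,
                                 fp = cf$fp, fn = cf$fn,
                                 accuracy = cf$accuracy, auc = cf$auc,
                                 cutoff = roc$cutoff))
  selrows <- rbind(selrows, data.frame(variant = vn, step = seq_along(sel$selected),
                                       feature = sel$selected))
  score_tab <- rbind(score_tab, data.frame(variant = vn,
                                           case_id = feats$case_id,
                                           score = sc, pr = yv))
}
write.csv(perf, "results/performance_by_variant.csv", row.names = FALSE)
write.csv(selrows, "results/selected_features.csv", row.names = FALSE)
write.csv(score_tab, "results/scores.csv", row.names = FALSE)
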