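#!/usr/bin/env Rscript
# Outcome statistics: group comparisons of clinical covariates between
# P/R and stable cases (chi-square / Fisher / Mann-Whitney), Kaplan-Meier
# progression-free survival split at the SVM-score cutoff with the
# log-rank test, and univariate -> multivariate Cox modelling.
#
# Requires 04_select_score.R.  Outputs: results/group_comparisons.csv,
# results/cox_univariate.csv, results/cox_multivariate.csv,
# results/km_curves.csv.

suppressMessages(library(pitradiomics))

rec <- read.csv("results/cohort.csv")
scores <- read.csv("results/scores.csv")
sc <- scores[scores$variant == "original", ]
rec$svm_score <- sc$score[match(rec$case_id, sc$case_id)]

vars <- c("sex_male", "age", "visual_disturbance", "headache",
          "sex_hormone_symptoms", "hypopituitarism", "hyperprolactinemia",
          "resection", "chiasm_decompressed", "knosp_high", "hardy_high",
          "chiasm_compression", "third_ventricle_compression",
          "hydrocephalus", "giant", "height_mm", "volume_cm3", "svm_score")
cmp <- do.call(rbind, lapply(vars, function(v) {
  out <- tryCatch(compare_groups(rec, v), error = function(e) NULL)
  if (is.null(out)) return(NULL)
  data.frame(variable = v, test = out$test, p = out$p)
}))
write.csv(cmp, "results/group_comparisons.csv", row.names = FALSE)
cat("variables with p < 0.05 between P/R and stable groups:\n  ",
    paste(cmp$variable[cmp$p < 0.05], collapse = ", "), "\n")

cutoff <- read.csv("results/performance_by_variant.csv")$cutoff[1]
km <- km_logrank(rec, function(r) ifelse(r$svm_score >= cutoff,
                                         "high score", "low score"))
s <- summary(km$fit)
write.csv(data.frame(group = as.character(s$strata), time = s$time,
                     surv = s$surv, n_risk = s$n.risk),
          "results/km_curves.csv", row.names = FALSE)
cat(sprintf("log-rank by SVM-score cutoff %.3f: chisq %.1f, p %.2g\n",
            cutoff, km$chisq, km$p))

covs <- c("sex_male", "age", "height_mm", "volume_cm3", "giant",
          "chiasm_decompressed", "svm_score")
uni <- cox_fit(rec, covs, mode = "univariate")
write.csv(uni, "results/cox_univariate.csv", row.names = FALSE)
multi <- tryCatch(cox_fit(rec, covs, mode = "multivariate"),
                  error = function(e) NULL)
if (!is.null(multi)) {
  write.csv(multi, "results/cox_multivariate.csv", row.names = FALSE)
  cat("multivariate model over univariate-significant covariates:\n")
  print(multi[, c("variable", "hr", "ci_low", "ci_high", "p")])
} else {
  cat("no covariate reached univariate p < 0.05; multivariate model skipped\n")
}
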