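#!/usr/bin/env Rscript
# Step 4 — ROC analysis of the six dynamic-index predictors.
#
# For PPV and SVV at baseline (T1), during the PEEP challenge (T2) and as
# PEEP-challenge deltas, computes the empirical ROC curve against the fluid
# responder label: AUC with Hanley-McNeil SE/CI and p-value against 0.5,
# the Youden-optimal cutoff, and the operating-point Se/Sp/PPV/NPV with
# Wald CIs. Also compares each delta's AUC to its baseline counterpart
# (paired Hanley-McNeil z-test). Writes results/roc_table.csv,
# results/roc_results.json and per-predictor curve coordinates under
# results/roc_curves/.

library(peepchallenge)

cohort <- read_cohort("results/cohort.csv")
predictors <- c("PPV_T1", "PPV_T2", "delta_ppv", "SVV_T1", "SVV_T2",
                "delta_svv")

tab <- roc_table(cohort, predictors)
write.csv(tab, "results/roc_table.csv", row.names = FALSE)

dir.create("results/roc_curves", showWarnings = FALSE)
curves <- lapply(predictors, function(p) {
  curve <- empirical_roc(cohort[[p]], cohort$responder, predictor = p)
  write.csv(data.frame(threshold = curve$thresholds,
                       sensitivity = curve$sensitivity,
                       specificity = curve$specificity),
            file.path("results/roc_curves", paste0(p, ".csv")),
            row.names = FALSE)
  curve
})
names(curves) <- predictors

if (requireNamespace("jsonlite", quietly = TRUE)) {
  res <- lapply(predictors, function(p) {
    r <- tab[tab$predictor == p, ]
    list(auc = r$auc, se = r$se_auc, ci = c(r$ci_low, r$ci_high),
         p_vs_null = r$p_vs_null, cutoff = r$cutoff,
         sensitivity = c(r$sens, r$sens_low, r$sens_high),
         specificity = c(r$spec, r$spec_low, r$spec_high),
         ppv = c(r$ppv, r$ppv_low, r$ppv_high),
         npv = c(r$npv, r$npv_low, r$npv_high))
  })
  names(res) <- predictors
  jsonlite::write_json(res, "results/roc_results.json", auto_unbox = TRUE,
                       digits = NA)
}

print(tab[, c("predictor", "auc", "ci_low", "ci_high", "p_vs_null",
              "cutoff", "sens", "spec")], row.names = FALSE, digits = 3)

cat("\nPaired AUC comparisons (delta vs baseline):\n")
for (pair in list(c("delta_ppv", "PPV_T1"), c("delta_svv", "SVV_T1"))) {
  cmp <- compare_aucs(curves[[pair[1]]], curves[[pair[2]]], paired = TRUE)
  cat(sprintf("  %s (AUC %.2f) vs %s (AUC %.2f): z = %.2f, p = %.3g\n",
              pair[1], cmp$auc_a, pair[2], cmp$auc_b, cmp$z_statistic,
              cmp$p_value))
}
cat("-> results/roc_table.csv, results/roc_results.json\n")
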