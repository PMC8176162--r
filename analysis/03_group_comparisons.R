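#!/usr/bin/env Rscript
# Step 3 — group comparison tables.
#
# Reproduces the published-style comparison layer on the simulated cohort:
# within-group changes across the PEEP challenge (T1 -> T2) and across fluid
# loading (T3 -> T4), paired t-test or Wilcoxon signed-rank by normality
# screen, plus a between-group contrast of each PEEP-challenge delta.
# Writes results/table_peep_challenge.csv and results/table_fluid_loading.csv.

library(peepchallenge)

cohort <- read_cohort("results/cohort.csv")

t12 <- change_table(cohort, "T1", "T2")
t34 <- change_table(cohort, "T3", "T4")
write.csv(t12, "results/table_peep_challenge.csv", row.names = FALSE)
write.csv(t34, "results/table_fluid_loading.csv", row.names = FALSE)

cat("PEEP challenge (T1 -> T2):\n")
print(t12[t12$variable %in% c("PPV", "SVV", "SV", "CI"), ],
      row.names = FALSE, digits = 3)
cat("\nFluid loading (T3 -> T4):\n")
print(t34[t34$variable %in% c("PPV", "SVV", "SV", "CI"), ],
      row.names = FALSE, digits = 3)

cat("\nBetween-group contrasts of the PEEP-challenge deltas:\n")
for (v in c("delta_ppv", "delta_svv")) {
  r <- compare_between_groups(cohort, v)
  cat(sprintf("  %s: %s, p = %.3g\n", v, r$test_used, r$p_value))
}
cat("-> results/table_peep_challenge.csv, results/table_fluid_loading.csv\n")
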