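#!/usr/bin/env Rscript
# Step 1 — simulate the study cohort.
#
# Draws a 40-patient cohort (18 fluid responders, 22 non-responders) from
# the packaged group distribution parameters: hemodynamic and respiratory
# variables at the four protocol time points (T1 zero-PEEP baseline, T2
# during the 10 cmH2O PEEP challenge, T3 second baseline after PEEP
# withdrawal, T4 after fluid loading), with the PEEP-challenge deltas
# computed from the drawn T1/T2 values. Writes results/cohort.csv.

library(peepchallenge)

seed <- 20210429
dir.create("results", showWarnings = FALSE)

cohort <- generate_cohort(n_responders = 18, n_nonresponders = 22,
                          seed = seed)
write_cohort(cohort, "results/cohort.csv")

cat(sprintf("simulated %d patients (%d responders, %d non-responders), seed %d\n",
            nrow(cohort), sum(cohort$responder), sum(!cohort$responder),
            seed))
cat(sprintf("truncated index draws: %d\n", attr(cohort, "n_truncated")))
agg <- aggregate(cbind(delta_ppv, delta_svv) ~ group, cohort, mean)
print(agg, row.names = FALSE)
cat("-> results/cohort.csv\n")
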