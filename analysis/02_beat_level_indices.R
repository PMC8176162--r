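#!/usr/bin/env Rscript
# Step 2 — verify the beat-level index path.
#
# Simulates beat series whose respiratory modulation depth encodes a known
# PPV/SVV target, recomputes the indices from the beats (per-cycle max/min
# envelope, averaged over three consecutive respiratory cycles, as a bedside
# monitor reports them), and tabulates the recovery error at monitor-like
# (6 beats/cycle) and dense (32 beats/cycle) sampling. Writes
# results/beat_recovery.csv.

library(peepchallenge)

set.seed(20210430)
dir.create("results", showWarnings = FALSE)

targets <- c(2, 4, 6, 8, 12, 20)
rows <- list()
for (bpc in c(6, 32)) {
  for (tg in targets) {
    computed <- replicate(20, {
      b <- generate_beats(target_ppv = tg, target_svv = tg,
                          heart_rate = bpc * 10, resp_rate = 10,
                          n_cycles = 4)
      averaged_reading(b, k = 3)$ppv
    })
    rows[[length(rows) + 1L]] <- data.frame(
      beats_per_cycle = bpc, target_ppv = tg,
      mean_computed = mean(computed),
      mean_abs_error = mean(abs(computed - tg)))
  }
}
tab <- do.call(rbind, rows)
write.csv(tab, "results/beat_recovery.csv", row.names = FALSE)

print(tab, row.names = FALSE, digits = 3)
cat("\nAt 6 beats/cycle the discrete sampling under-reads the modulation\n")
cat("envelope (as a monitor does); at 32 beats/cycle recovery is within\n")
cat("half a percentage point.\n-> results/beat_recovery.csv\n")
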