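#!/usr/bin/env Rscript
# Parameter-recovery experiment: how reliably does the pipeline recover the
# true host-range category, standardised diet breadth, and the positive
# breadth-occurrence effect, as a function of the number of loads sampled
# per bee species?

library(pollendiet)

dir.create("results/recovery", recursive = TRUE, showWarnings = FALSE)

scenario <- foraging_scenario(seed = 20260103)
rec <- suppressWarnings(
  recovery_experiment(scenario, n_loads_grid = c(3, 10, 20),
                      n_replicates = 30, target_loads = 3,
                      seed = 20260103))

cat("Category recovery rate by template and sample size:\n")
print(rec$category_recovery, row.names = FALSE)
cat("\nRarefied-breadth bias (estimated - true, at a 3-load standard):\n")
print(rec$breadth_bias, row.names = FALSE)
cat("\nBreadth-occurrence fit across replicates:\n")
print(rec$occurrence_fit, row.names = FALSE)

write.csv(rec$category_recovery, "results/recovery/category_recovery.csv",
          row.names = FALSE)
write.csv(rec$breadth_bias, "results/recovery/breadth_bias.csv",
          row.names = FALSE)
write.csv(rec$occurrence_fit, "results/recovery/occurrence_fit.csv",
          row.names = FALSE)

cat("\nSmall samples mischaracterise: compare recovery at 3 vs 20 loads",
    "above.\nOutputs in results/recovery.\n")
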