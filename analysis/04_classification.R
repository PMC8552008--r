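#!/usr/bin/env Rscript
# Latent-space classification: movement class (flat vs stair) and
# individual identity (8 flat-ground subjects) from the 2-D latent spaces
# of PCA, the pose autoencoder and the movement autoencoder; 10 repeated
# trainings per autoencoder and a Kolmogorov-Smirnov comparison of the
# pose-AE vs move-AE error distributions. Writes
# results/classification_runs.csv and results/classification_summary.csv.
#
#   Rscript analysis/04_classification.R [--reps 10] [--seed 7]

suppressPackageStartupMessages(library(gaitlatent))
args <- commandArgs(trailingOnly = TRUE)
opt <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
reps <- as.integer(opt("--reps", "10"))
seed <- as.integer(opt("--seed", "7"))
prep <- readRDS("scratch/prep.rds")

pose_cfg <- pose_ae_config(iters = 350, lr = 2e-3)
move_cfg <- move_ae_config(iters = 300, lr = 3e-3)

runs <- rbind(
  run_task("movement", prep, repetitions = reps, seed = seed,
           pose_config = pose_cfg, move_config = move_cfg),
  run_task("individual", prep, repetitions = reps, seed = seed,
           pose_config = pose_cfg, move_config = move_cfg))
write.csv(runs, "results/classification_runs.csv", row.names = FALSE)
summ <- summarize_runs(runs)
write.csv(summ, "results/classification_summary.csv", row.names = FALSE)
print(summ, row.names = FALSE, digits = 3)

ks <- do.call(rbind, lapply(split(runs, runs$task), function(d) {
  k <- compare_runs(d$error[d$reducer == "pose_ae"],
                    d$error[d$reducer == "move_ae"])
  data.frame(task = d$task[1], comparison = "pose_ae vs move_ae",
             ks_statistic = k$statistic, p_value = k$p_value)
}))
write.csv(ks, "results/ks_comparisons.csv", row.names = FALSE)
cat("\nKS comparison of pose-AE vs move-AE error distributions:\n")
print(ks, row.names = FALSE, digits = 3)
for (tk in unique(summ$task)) {
  ord <- summ$reducer[summ$task == tk][order(summ$median_error[summ$task == tk])]
  cat(sprintf("\n%s task, reducers from lowest to highest median error: %s\n",
              tk, paste(ord, collapse = " < ")))
}
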