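#!/usr/bin/env Rscript
# Latent-structure probes: (a) phase-ordered cyclic loops for steady gait
# in every reducer's latent space; (b) forward vs time-reversed gait —
# separable for the movement autoencoder, at chance for pose-level
# reducers, and back to chance when window frames are shuffled. Writes
# results/latent_structure.csv (and latent scatter figures when ggplot2
# is available).
#
#   Rscript analysis/05_latent_structure.R [--seed 7]

suppressPackageStartupMessages(library(gaitlatent))
args <- commandArgs(trailingOnly = TRUE)
opt <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
seed <- as.integer(opt("--seed", "7"))

## (a) cyclic structure: one flat-ground subject, one minute of steady gait
prep1 <- preprocess_study(generate_study(1, 0, 0, duration = 60,
                                         seed = child_seed(seed, "cyclic")))
rec <- prep1$recordings[[1]]
pose_all <- sample_poses(rec, prep1$standardizer, stride = 1)
win_all <- sample_windows(rec, prep1$standardizer, stride = 2)
pm <- train_pose_ae(prep1$poses$x,
                    pose_ae_config(iters = 350, lr = 2e-3,
                                   seed = child_seed(seed, "cyclic/pose")))
mm <- train_move_ae(prep1$windows$x,
                    move_ae_config(iters = 300, lr = 3e-3,
                                   seed = child_seed(seed, "cyclic/move")))
align <- data.frame(
  probe = "phase_alignment",
  reducer = c("pca", "pose_ae", "move_ae"),
  value = c(
    latent_phase_alignment(encode(fit_pca(prep1$poses$x), pose_all$x, k = 2),
                           pose_all$info$cycle_phase),
    latent_phase_alignment(encode(pm, pose_all$x), pose_all$info$cycle_phase),
    latent_phase_alignment(encode(mm, win_all$x), win_all$info$cycle_phase)))

## (b) temporal sensitivity: forward vs reversed windows
prep2 <- preprocess_study(generate_study(2, 0, 0, duration = 30,
                                         seed = child_seed(seed, "reversal")))
W <- prep2$windows$x
n <- dim(W)[1]
comb <- array(0, c(2 * n, 60, 14))
comb[1:n, , ] <- W
comb[(n + 1):(2 * n), , ] <- reverse_windows(W)
lab <- rep(c("fwd", "rev"), each = n)
mm2 <- train_move_ae(comb, move_ae_config(iters = 1200, lr = 3e-3,
                                          seed = child_seed(seed, "reversal/move")))
pf <- windows_as_poses(W)
pr <- windows_as_poses(reverse_windows(W))
px <- rbind(pf$x, pr$x)
plab <- rep(c("fwd", "rev"), c(nrow(pf$x), nrow(pr$x)))
pm2 <- train_pose_ae(px, pose_ae_config(iters = 350, lr = 2e-3,
                                        seed = child_seed(seed, "reversal/pose")))
sh <- shuffle_window_frames(comb, seed = child_seed(seed, "reversal/shuffle"))
ms <- train_move_ae(sh, move_ae_config(iters = 400, lr = 3e-3,
                                       seed = child_seed(seed, "reversal/control")))
rev_err <- data.frame(
  probe = "reversal_error",
  reducer = c("pca", "pose_ae", "move_ae", "move_ae_shuffled_control"),
  value = c(classify_latent(encode(fit_pca(px), px, k = 2), plab),
            classify_latent(encode(pm2, px), plab),
            classify_latent(encode(mm2, comb), lab),
            classify_latent(encode(ms, sh), lab)))

out <- rbind(align, rev_err)
dir.create("results", showWarnings = FALSE)
write.csv(out, "results/latent_structure.csv", row.names = FALSE)
print(out, row.names = FALSE, digits = 3)
cat("\nSteady gait forms phase-ordered latent loops in all three reducers.\n")
cat("Only the movement autoencoder separates forward from backward walking;\n")
cat("shuffling frames within windows destroys that separation.\n")

if (requireNamespace("ggplot2", quietly = TRUE)) {
  ggplot2::ggsave("results/latent_movement.pdf",
                  plot_latent(encode(mm2, comb), lab,
                              "Move-AE latent: forward vs reversed"),
                  width = 5, height = 4)
}
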