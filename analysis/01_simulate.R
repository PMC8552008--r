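#!/usr/bin/env Rscript
# Generate the synthetic gait study: 8 flat-ground, 11 stair and 13
# natural-movement subjects, 60 s each at 60 Hz, and write every recording
# as CSV (+ JSON sidecar) under results/data/.
#
#   Rscript analysis/01_simulate.R [--seed 7] [--duration 60] [--out results/data]

suppressPackageStartupMessages(library(gaitlatent))
args <- commandArgs(trailingOnly = TRUE)
opt <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
seed <- as.integer(opt("--seed", "7"))
duration <- as.numeric(opt("--duration", "60"))
out <- opt("--out", "results/data")
dir.create(out, recursive = TRUE, showWarnings = FALSE)

study <- generate_study(8, 11, 13, duration = duration, seed = seed)
for (id in names(study$recordings)) {
  write_recording(study$recordings[[id]], file.path(out, paste0(id, ".csv")))
}
cadences <- vapply(study$profiles, `[[`, numeric(1), "cadence")
cat(sprintf("wrote %d recordings (%.0f s each) to %s\n",
            length(study$recordings), duration, out))
cat(sprintf("subject cadences span %.2f-%.2f strides/s\n",
            min(cadences), max(cadences)))
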