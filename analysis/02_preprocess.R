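#!/usr/bin/env Rscript
# Preprocess the simulated study: drop the knee frontal/transverse
# channels, filter the natural stream by pelvic velocity, standardize by
# the pooled statistics of all three datasets, and sample poses (every 10
# frames) and one-second windows. Writes a preprocessing summary table.
#
#   Rscript analysis/02_preprocess.R [--in results/data] [--out results]

suppressPackageStartupMessages(library(gaitlatent))
args <- commandArgs(trailingOnly = TRUE)
opt <- function(flag, default) {
  i <- which(args == flag)
  if (length(i) == 1 && i < length(args)) args[i + 1] else default
}
indir <- opt("--in", "results/data")
outdir <- opt("--out", "results")
dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
dir.create("scratch", showWarnings = FALSE)

paths <- list.files(indir, pattern = "\\.csv$", full.names = TRUE)
study <- list(recordings = lapply(paths, read_recording))
names(study$recordings) <- vapply(study$recordings, `[[`, character(1), "subject_id")

prep <- preprocess_study(study)
saveRDS(prep, "scratch/prep.rds")  # intermediate, consumed by later steps

info <- prep$poses$info
summ <- do.call(rbind, lapply(split(info, info$activity), function(d) {
  data.frame(activity = d$activity[1], subjects = length(unique(d$subject)),
             poses = nrow(d))
}))
summ$windows <- as.numeric(table(prep$windows$info$activity)[summ$activity])
write.csv(summ, file.path(outdir, "preprocessing_summary.csv"), row.names = FALSE)
print(summ, row.names = FALSE)
cat(sprintf("pooled standardizer: %d channels, natural stream filtered to %d active segments\n",
            length(prep$standardizer$mean),
            sum(vapply(prep$recordings, function(r)
              identical(r$activity, "natural"), logical(1)))))
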