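#!/usr/bin/env Rscript
# Step 2: preprocess the raw cohorts into normalized and averaged curves.
#
# Each trace is background-corrected, normalized so the mean over
# pre-bleach frames 10-20 is 100 (RFI), and re-zeroed at the bleach frame;
# cells are then averaged per condition. Pre-bleach intensity, the total
# Pol II level proxy, is summarized relative to the unperturbed condition.

library(polfrap)

trace_files <- list.files("results/cohorts", pattern = "^traces_.*\\.csv$",
                          full.names = TRUE)
stopifnot(length(trace_files) > 0)
dir.create("results/curves", recursive = TRUE, showWarnings = FALSE)

all_curves <- list()
for (path in trace_files) {
  traces <- read_frap_traces(path)
  curves <- preprocess_traces(traces)
  label <- curves[[1]]$condition
  slug <- gsub("[^A-Za-z0-9]+", "_", label)
  write_frap_csv(curves, file.path("results/curves",
                                   paste0("normalized_", slug, ".csv")))
  mc <- average_curves(curves)
  write_frap_csv(mc, file.path("results/curves", paste0("mean_", slug, ".csv")))
  message(sprintf("%s: %d cells averaged, first post-bleach RFI %.1f",
                  label, mc$n_cells, mc$rfi_mean[mc$times >= 0][1]))
  all_curves <- c(all_curves, curves)
}

levels <- prebleach_level_summary(all_curves, reference = "0 J")
write.csv(levels, "results/curves/prebleach_levels.csv", row.names = FALSE)
message("Pre-bleach Pol II level proxy (relative to 0 J):")
print(levels)
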