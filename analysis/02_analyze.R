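#!/usr/bin/env Rscript
# Run the grasp-bias reanalysis on the dataset written by 01_simulate.R:
# exclude long-axis grasps, compute per-participant and group medoid grasps,
# measure the 150-degree bias, build the visibility and reach predictions at
# 60 degrees, and compare them with a paired t-test.

suppressPackageStartupMessages(library(graspbias))

path <- "results/synthetic_grasps.csv"
if (!file.exists(path)) stop("run analysis/01_simulate.R first (missing ", path, ")")

records <- load_records(path, verbose = TRUE)
result <- run_analysis(records, analysis_config(), verbose = TRUE)
print(result)
report(result, "results/analysis_report.json")
cat("-> results/analysis_report.json (+ .txt)\n")
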