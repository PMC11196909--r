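#!/usr/bin/env Rscript
# Step 2: run the activity-space pipeline on the simulated cohort.
#
# Reads results/sim/{gps,homes,reports}.csv, drops fixes outside the
# sub-Saharan bounding box, builds trajectories, computes per-participant
# mobility and behavior-location measures, and writes all output tables to
# results/pipeline/.

library(activityspace)

stopifnot(file.exists("results/sim/gps.csv")) # run analysis/01_simulate.R first

res <- run_pipeline(
  gps = "results/sim/gps.csv",
  homes = "results/sim/homes.csv",
  reports = "results/sim/reports.csv",
  out_dir = "results/pipeline"
)

pm <- res$participant_measures
cat("\nPer-participant measures (", nrow(pm), " participants):\n", sep = "")
cat("  weekly km:        median", round(median(pm$weekly_km)), "\n")
cat("  unique locations: median", round(median(pm$n_unique_locations)), "\n")
cat("  % outside 100 m:  median", round(median(pm$pct_outside_100m)), "\n")
cat("Outputs in results/pipeline/: participant_measures.csv, linked_reports.csv,\n")
cat("  excluded_points.csv, cohort_table.csv, behavior_table.csv, behavior_counts.csv\n")
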