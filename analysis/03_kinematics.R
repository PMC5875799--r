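#!/usr/bin/env Rscript
# Extract the kinematic fields of every plant in the cohort: orientation,
# curvature, REGR (1-D image correlation on the marker profiles) and the
# material curvature derivative; summarize oscillations, temporal
# averages, coupling and morphometrics.

suppressPackageStartupMessages(library(coleokin))
rep <- suppressWarnings(
  run_pipeline("results/cohort_data", "results/kinematics"))
cat("analysed", nrow(rep$summaries), "plants;",
    length(rep$failures), "failures\n")
print(rep$summaries[, c("plant_id", "group", "Tp_regr", "vp_regr",
                        "coupling_r", "B", "observed_overshoot")],
      digits = 3, row.names = FALSE)
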