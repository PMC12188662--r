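#!/usr/bin/env Rscript
# Stage 3: voxel-calibrated volumetrics per stack and ROI -- total disSOD1
# volume and its partition by compartment (within neurons / astrocytes /
# elsewhere), astrocyte volume, neuron counts and densities -- then the
# combined cohort table.

source("analysis/00_config.R")

cfg <- cohort_config()
run_pipeline(cfg, RUN_DIR, stages = "quantify")

comb <- read.csv(file.path(RUN_DIR, "quant/combined.csv"))
write.csv(comb, file.path(RESULTS_DIR, "combined_reports.csv"),
          row.names = FALSE)

full <- comb[comb$roi_name == "SNc+SNr", ]
cat("Whole-SN disSOD1 volume (um^3) per stack:\n")
print(setNames(round(full$dis_total_um3, 1), full$stack_id))
cat("Compartment conservation (max |sum - total|):",
    max(abs(full$dis_in_neuron_um3 + full$dis_in_astro_um3 +
              full$dis_other_um3 - full$dis_total_um3)), "um^3\n")
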