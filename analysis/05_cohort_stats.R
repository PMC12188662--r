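#!/usr/bin/env Rscript
# Stage 5: cohort statistics -- per-group mean +/- SEM of whole-SN disSOD1
# volume, directional fold changes against the disease_vehicle reference,
# reference-scaled compartment percentages, and dopamine turnover.

source("analysis/00_config.R")

cfg <- cohort_config()
run_pipeline(cfg, RUN_DIR, stages = "stats")

summ <- read.csv(file.path(RUN_DIR, "stats/summaries.csv"))
fc <- read.csv(file.path(RUN_DIR, "stats/fold_changes.csv"))
write.csv(summ, file.path(RESULTS_DIR, "group_summaries.csv"), row.names = FALSE)
write.csv(fc, file.path(RESULTS_DIR, "fold_changes.csv"), row.names = FALSE)

cat("Group means (whole-SN disSOD1 volume, um^3):\n")
print(summ[, c("group", "n", "mean", "sem")])
key <- fc[fc$group == "disease_treated", ]
cat(sprintf("Treatment effect: %.2f-fold %s vs disease_vehicle\n",
            key$fold, key$direction))

# compartment shares scaled to the reference group's whole-SN total
comb <- read.csv(file.path(RUN_DIR, "quant/combined.csv"))
bm <- read.csv(file.path(RUN_DIR, "sim/blind_map.csv"))
comb$group <- sub("_[0-9]+$", "", bm$animal_id[match(comb$stack_id, bm$code)])
full <- comb[comb$roi_name == "SNc+SNr", ]
ref_total <- mean(full$dis_total_um3[full$group == "disease_vehicle"])
shares <- do.call(rbind, lapply(split(full, full$group), function(g) {
  data.frame(group = g$group[1],
             pct_in_neuron = reference_scaled_percentages(
               mean(g$dis_in_neuron_um3), ref_total),
             pct_in_astro = reference_scaled_percentages(
               mean(g$dis_in_astro_um3), ref_total),
             pct_other = reference_scaled_percentages(
               mean(g$dis_other_um3), ref_total))
}))
write.csv(shares, file.path(RESULTS_DIR, "compartment_percentages.csv"),
          row.names = FALSE)
cat("Compartment percentages (scaled to disease_vehicle whole-SN total):\n")
print(shares, row.names = FALSE, digits = 3)

nc <- read.csv(file.path(RUN_DIR, "stats/neurochem_turnover.csv"))
write.csv(nc, file.path(RESULTS_DIR, "neurochem_turnover.csv"),
          row.names = FALSE)
cat("Mean dopamine turnover per group:\n")
print(round(tapply(nc$turnover, nc$group, mean), 3))
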