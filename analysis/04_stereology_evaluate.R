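#!/usr/bin/env Rscript
# Stage 4: spinal motor-neuron stereology on synthetic sections (ISL-1
# nuclei with proximal ChAT, counts normalized per mm of cord) and
# validation of the neuron segmentation against phantom ground truth
# (instance-matching F1, count correlation).

source("analysis/00_config.R")

cfg <- cohort_config()
run_pipeline(cfg, RUN_DIR, stages = c("stereology", "evaluate"))

ster <- read.csv(file.path(RUN_DIR, "stereology/motor_neuron_counts.csv"))
write.csv(ster, file.path(RESULTS_DIR, "motor_neuron_counts.csv"),
          row.names = FALSE)
cat("Motor neurons per mm of cord (", unique(ster$n_sections), "sections x",
    unique(ster$section_thickness_um), "um =",
    unique(ster$represented_length_mm), "mm ):\n")
print(setNames(ster$count_per_mm, ster$section_set_id))

ev <- jsonlite::fromJSON(file.path(RUN_DIR, "evaluate/evaluation.json"))
cat(sprintf("Segmentation vs truth: TP=%d FP=%d FN=%d F1=%.3f\n",
            ev$TP, ev$FP, ev$FN, ev$f1))
jsonlite::write_json(ev, file.path(RESULTS_DIR, "evaluation.json"),
                     auto_unbox = TRUE, digits = NA)
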