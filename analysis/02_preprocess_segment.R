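#!/usr/bin/env Rscript
# Stage 2: threshold the disSOD1 channel, run the GFAP astrocyte pipeline
# (background subtraction, Yen threshold, mask smoothing, size filter), and
# segment dopamine neurons: per-slice 2D labels stitched into 3D cells by
# the IoU >= 0.25 linkage rule, then cleaned morphologically.

source("analysis/00_config.R")

cfg <- cohort_config()
run_pipeline(cfg, RUN_DIR, stages = c("preprocess", "segment"))

seg_files <- list.files(file.path(RUN_DIR, "seg"), pattern = "tiff$",
                        full.names = TRUE)
counts <- vapply(seg_files, function(f) count_instances(read_labels(f)),
                 integer(1))
cat("Segmented neuron instances per stack:\n")
print(setNames(counts, basename(seg_files)))
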