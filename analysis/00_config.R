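# Shared configuration for the analysis scripts: a four-group synthetic
# cohort emulating a disease-model x treatment design. Group multipliers
# program the relative disSOD1 aggregate burden; the key contrast
# (disease_vehicle vs disease_treated) is a programmed 4.4-fold effect.
# Stacks and intermediates go under scratch/ (regenerable), tables under
# results/.

library(voxquant)

cohort_config <- function(seed = 20260921L) {
  pipeline_config(
    base_spec = phantom_spec(noise_sd = 0, blur_sigma_um = 0, seed = 1L),
    group_effects = c(disease_vehicle = 4.4,
                      disease_treated = 1.0,
                      control_vehicle = 1.2,
                      wildtype_vehicle = 0.25),
    n_per_group = 3L,
    seed = seed,
    stats = list(reference_group = "disease_vehicle"))
}

RUN_DIR <- "scratch/pipeline"
RESULTS_DIR <- "results"
dir.create(RUN_DIR, recursive = TRUE, showWarnings = FALSE)
dir.create(RESULTS_DIR, recursive = TRUE, showWarnings = FALSE)
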