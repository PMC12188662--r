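PIPELINE_STAGES <- c("simulate", "preprocess", "segment", "quantify",
                     "stereology", "evaluate", "stats")

#' Build and validate a pipeline configuration
#'
#' Central parameter record for [run_pipeline()]. Every parameter is echoed
#' into the run manifest; unknown keys are rejected so typos cannot
#' silently fall back to defaults.
#'
#' @param base_spec [phantom_spec()] describing one reference animal.
#' @param group_effects named positive multipliers on aggregate burden.
#' @param n_per_group animals per group.
#' @param seed master seed.
#' @param dis_threshold manual disSOD1 intensity threshold.
#' @param th_threshold intensity threshold for the built-in TH segmenter.
#' @param astro list: `blur_sigma_um`, `background_levels`, `method`,
#'   `min_volume_um3` for the GFAP pipeline.
#' @param stitching list: `iou_min`, `min_volume_um3`.
#' @param evaluation list: `match_iou_min`.
#' @param stereology list: `proximity_um`, `thickness_um`, `n_sections`,
#'   `n_nuclei`, `pixel_spacing_um`.
#' @param stats list: `reference_group`, `metric`, `roi`,
#'   `remove_outliers`.
#' @param neurochem list: `group_means` (named list of `c(DA, DOPAC, HVA)`)
#'   and `noise_sd`; `NULL` for per-group defaults scaled off the first
#'   group.
#' @param blind assign random codes to stack ids and un-blind only at the
#'   stats stage.
#' @return validated config list of class `pipeline_config`.
#' @export
pipeline_config <- function(base_spec = phantom_spec(),
                            group_effects = c(vehicle = 4, treated = 1),
                            n_per_group = 2L,
                            seed = 1L,
                            dis_threshold = 2000,
                            th_threshold = 1200,
                            astro = list(),
                            stitching = list(),
                            evaluation = list(),
                            stereology = list(),
                            stats = list(),
                            neurochem = NULL,
                            blind = FALSE) {
  merge_known <- function(given, defaults, what) {
    unknown <- setdiff(names(given), names(defaults))
    if (length(unknown)) {
      stop(sprintf("unknown %s key(s): %s", what,
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    defaults[names(given)] <- given
    defaults
  }
  cfg <- list(
    base_spec = base_spec,
    group_effects = group_effects,
    n_per_group = as.integer(n_per_group),
    seed = as.integer(seed),
    dis_threshold = dis_threshold,
    th_threshold = th_threshold,
    astro = merge_known(astro, list(blur_sigma_um = 0.5,
                                    background_levels = 25,
                                    method = "yen",
                                    min_volume_um3 = 8), "astro"),
    stitching = merge_known(stitching, list(iou_min = 0.25,
                                            min_volume_um3 = 8), "stitching"),
    evaluation = merge_known(evaluation, list(match_iou_min = 0.5),
                             "evaluation"),
    stereology = merge_known(stereology, list(proximity_um = 5,
                                              thickness_um = 30,
                                              n_sections = 50L,
                                              n_nuclei = 9L,
                                              pixel_spacing_um = 0.5),
                             "stereology"),
    stats = merge_known(stats, list(reference_group = names(group_effects)[1],
                                    metric = "dis_total_um3",
                                    roi = "SNc+SNr",
                                    remove_outliers = FALSE), "stats"),
    neurochem = neurochem,
    blind = isTRUE(blind))
  stopifnot(inherits(cfg$base_spec, "phantom_spec"))
  if (is.null(names(cfg$group_effects))) {
    stop("group_effects must be named", call. = FALSE)
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Scalar fields map directly onto [pipeline_config()] arguments; the
#' `base_spec` block holds [phantom_spec()] arguments.
#'
#' @param path YAML file.
#' @return a `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  spec_args <- y$base_spec
  if (!is.null(spec_args)) {
    if (!is.null(spec_args$aggregate_placement)) {
      spec_args$aggregate_placement <- unlist(spec_args$aggregate_placement)
    }
    if (!is.null(spec_args$aggregate_radius_um)) {
      spec_args$aggregate_radius_um <- unlist(spec_args$aggregate_radius_um)
    }
  }
  y$base_spec <- do.call(phantom_spec, if (is.null(spec_args)) list() else spec_args)
  if (!is.null(y$group_effects)) y$group_effects <- unlist(y$group_effects)
  do.call(pipeline_config, y)
}

# deterministic content hash of an R object (used for stage skipping)
content_hash <- function(obj) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  writeBin(serialize(obj, NULL, version = 2), tmp)
  unname(tools::md5sum(tmp))
}

stage_manifest_path <- function(out_dir, stage) {
  file.path(out_dir, "manifests", paste0(stage, ".json"))
}

stage_up_to_date <- function(out_dir, stage, hash) {
  mp <- stage_manifest_path(out_dir, stage)
  if (!file.exists(mp)) return(FALSE)
  m <- tryCatch(jsonlite::fromJSON(mp), error = function(e) NULL)
  if (is.null(m) || !identical(as.character(m$hash), hash)) return(FALSE)
  all(file.exists(file.path(out_dir, unlist(m$outputs))))
}

write_stage_manifest <- function(out_dir, stage, hash, outputs, params) {
  mp <- stage_manifest_path(out_dir, stage)
  dir.create(dirname(mp), recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(list(stage = stage, hash = hash, outputs = outputs,
                            params = params),
                       mp, auto_unbox = TRUE, digits = NA, force = TRUE)
}

require_stage_output <- function(out_dir, stage, needed_by, files) {
  missing <- files[!file.exists(file.path(out_dir, files))]
  if (length(missing)) {
    stop(sprintf("dependency error: stage '%s' requires outputs of stage '%s' (missing: %s)",
                 needed_by, stage, paste(missing, collapse = ", ")),
         call. = FALSE)
  }
}

animal_ids <- function(cfg) {
  unlist(lapply(names(cfg$group_effects),
                function(g) sprintf("%s_%02d", g, seq_len(cfg$n_per_group))))
}

# blinding map: random codes for stack ids, derived from the master seed
blind_map <- function(cfg) {
  ids <- animal_ids(cfg)
  codes <- with_seed(cfg$seed + 7L,
                     sprintf("blind_%03d", sample.int(999L, length(ids))))
  data.frame(animal_id = ids, code = if (cfg$blind) codes else ids,
             stringsAsFactors = FALSE)
}

#' Run the phantom-to-statistics pipeline
#'
#' Orchestrates simulate, preprocess, segment, quantify, stereology,
#' evaluate and stats over a synthetic cohort, writing per-stage outputs,
#' manifests and logs under `out_dir`. Stage outputs are content-addressed:
#' a stage whose parameters and upstream hashes are unchanged and whose
#' outputs exist is skipped on re-run. Two runs with identical config and
#' seed produce byte-identical result tables.
#'
#' @param config a `pipeline_config`.
#' @param out_dir run directory (created if needed).
#' @param stages subset of stages to run (in canonical order); later stages
#'   raise a dependency error when upstream outputs are absent.
#' @return named list of key result paths, invisibly.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = PIPELINE_STAGES) {
  stopifnot(inherits(config, "pipeline_config"))
  stages <- match.arg(stages, PIPELINE_STAGES, several.ok = TRUE)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- config
  ids <- animal_ids(cfg)
  bmap <- blind_map(cfg)
  code_of <- setNames(bmap$code, bmap$animal_id)
  sp <- cfg$base_spec$voxel_spacing_um
  results <- list()

  hash_sim <- content_hash(list("simulate", unclass(cfg$base_spec),
                                cfg$group_effects, cfg$n_per_group, cfg$seed,
                                cfg$blind, cfg$neurochem))
  sim_files <- c(paste0("sim/", code_of[ids], "_stack.tiff"),
                 paste0("sim/", code_of[ids], "_truth_neuron.tiff"),
                 paste0("sim/", code_of[ids], "_truth_aggregate.tiff"),
                 paste0("sim/", code_of[ids], "_roi_SNc.tiff"),
                 "sim/cohort_truth.csv", "sim/neurochem.csv",
                 "sim/blind_map.csv")
  if ("simulate" %in% stages) {
    if (stage_up_to_date(out_dir, "simulate", hash_sim)) {
      message("stage simulate: up to date, skipped")
    } else {
      dir.create(file.path(out_dir, "sim"), showWarnings = FALSE)
      cohort <- generate_cohort(cfg$base_spec, cfg$group_effects,
                                cfg$n_per_group, cfg$seed)
      for (an in cohort$animals) {
        code <- code_of[[an$animal_id]]
        an$stack$source_id <- code
        write_stack(an$stack, file.path(out_dir, "sim",
                                        paste0(code, "_stack.tiff")))
        write_labels(an$truth$labels$neuron,
                     file.path(out_dir, "sim",
                               paste0(code, "_truth_neuron.tiff")))
        write_labels(an$truth$labels$aggregate,
                     file.path(out_dir, "sim",
                               paste0(code, "_truth_aggregate.tiff")))
        write_roi_mask(an$truth$rois$SNc,
                       file.path(out_dir, "sim",
                                 paste0(code, "_roi_SNc.tiff")))
      }
      truth_tab <- cohort$table
      truth_tab$code <- unname(code_of[truth_tab$animal_id])
      write.csv(truth_tab, file.path(out_dir, "sim/cohort_truth.csv"),
                row.names = FALSE)
      gm <- cfg$neurochem$group_means
      if (is.null(gm)) {
        gm <- lapply(seq_along(cfg$group_effects), function(i)
          c(10, 2, 3) * (1 + 0.2 * (i - 1)))
        names(gm) <- names(cfg$group_effects)
      }
      nc <- generate_neurochem_table(gm,
                                     noise_sd = if (is.null(cfg$neurochem$noise_sd)) 0.5
                                                else cfg$neurochem$noise_sd,
                                     n_per_group = cfg$n_per_group,
                                     seed = cfg$seed + 13L)
      write.csv(nc, file.path(out_dir, "sim/neurochem.csv"), row.names = FALSE)
      write.csv(bmap, file.path(out_dir, "sim/blind_map.csv"), row.names = FALSE)
      write_stage_manifest(out_dir, "simulate", hash_sim, sim_files,
                           list(seed = cfg$seed))
    }
  }

  hash_pre <- content_hash(list("preprocess", hash_sim, cfg$dis_threshold,
                                cfg$astro))
  pre_files <- c(paste0("pre/", code_of[ids], "_dis_mask.tiff"),
                 paste0("pre/", code_of[ids], "_astro_mask.tiff"))
  if ("preprocess" %in% stages) {
    require_stage_output(out_dir, "simulate", "preprocess", sim_files)
    if (stage_up_to_date(out_dir, "preprocess", hash_pre)) {
      message("stage preprocess: up to date, skipped")
    } else {
      dir.create(file.path(out_dir, "pre"), showWarnings = FALSE)
      for (id in ids) {
        code <- code_of[[id]]
        st <- read_stack(file.path(out_dir, "sim", paste0(code, "_stack.tiff")))
        dis <- manual_threshold(get_channel(st, "disSOD1"), cfg$dis_threshold,
                                source_channel = "disSOD1")
        astro <- preprocess_astro_channel(get_channel(st, "GFAP"),
                                          st$voxel_spacing_um,
                                          blur_sigma_um = cfg$astro$blur_sigma_um,
                                          background_levels = cfg$astro$background_levels,
                                          method = cfg$astro$method,
                                          min_volume_um3 = cfg$astro$min_volume_um3)
        write_roi_mask(as_mask_array(dis),
                       file.path(out_dir, "pre", paste0(code, "_dis_mask.tiff")))
        write_roi_mask(as_mask_array(astro),
                       file.path(out_dir, "pre", paste0(code, "_astro_mask.tiff")))
      }
      write_stage_manifest(out_dir, "preprocess", hash_pre, pre_files,
                           list(dis_threshold = cfg$dis_threshold,
                                astro = cfg$astro))
    }
  }

  hash_seg <- content_hash(list("segment", hash_sim, cfg$th_threshold,
                                cfg$stitching))
  seg_files <- paste0("seg/", code_of[ids], "_neuron_labels.tiff")
  if ("segment" %in% stages) {
    require_stage_output(out_dir, "simulate", "segment", sim_files)
    if (stage_up_to_date(out_dir, "segment", hash_seg)) {
      message("stage segment: up to date, skipped")
    } else {
      dir.create(file.path(out_dir, "seg"), showWarnings = FALSE)
      segmenter <- builtin_segmenter(cfg$th_threshold)
      for (id in ids) {
        code <- code_of[[id]]
        st <- read_stack(file.path(out_dir, "sim", paste0(code, "_stack.tiff")))
        sl <- segment_slices(get_channel(st, "TH"), segmenter)
        lv <- stitch_slices(sl, iou_min = cfg$stitching$iou_min,
                            voxel_spacing_um = st$voxel_spacing_um,
                            segmenter_id = "builtin_threshold")
        lv <- morph_cleanup(lv, cfg$stitching$min_volume_um3)
        write_labels(lv, file.path(out_dir, "seg",
                                   paste0(code, "_neuron_labels.tiff")))
      }
      write_stage_manifest(out_dir, "segment", hash_seg, seg_files,
                           list(th_threshold = cfg$th_threshold,
                                stitching = cfg$stitching))
    }
  }

  hash_q <- content_hash(list("quantify", hash_sim, hash_pre, hash_seg))
  q_files <- c(paste0("quant/", code_of[ids], "_report.csv"),
               "quant/combined.csv")
  if ("quantify" %in% stages) {
    require_stage_output(out_dir, "simulate", "quantify", sim_files)
    require_stage_output(out_dir, "preprocess", "quantify", pre_files)
    require_stage_output(out_dir, "segment", "quantify", seg_files)
    if (stage_up_to_date(out_dir, "quantify", hash_q)) {
      message("stage quantify: up to date, skipped")
    } else {
      dir.create(file.path(out_dir, "quant"), showWarnings = FALSE)
      per_paths <- character(0)
      for (id in ids) {
        code <- code_of[[id]]
        st <- read_stack(file.path(out_dir, "sim", paste0(code, "_stack.tiff")))
        dims <- dim(st$data)[2:4]
        dis <- read_labels(file.path(out_dir, "pre",
                                     paste0(code, "_dis_mask.tiff"))) > 0L
        astro <- read_labels(file.path(out_dir, "pre",
                                       paste0(code, "_astro_mask.tiff"))) > 0L
        # masks were stored as 0/255 8-bit via write_roi_mask; re-read binary
        dis <- array(dis, dims); astro <- array(astro, dims)
        labs <- read_labels(file.path(out_dir, "seg",
                                      paste0(code, "_neuron_labels.tiff")))
        rois <- read_roi_masks(c("SNc" = file.path(out_dir, "sim",
                                                   paste0(code, "_roi_SNc.tiff"))),
                               st)
        rois <- list("SNc" = rois[["SNc"]],
                     "SNc+SNr" = array(TRUE, dims))
        rep <- quantify_stack(code, dis, labs, astro, rois,
                              st$voxel_spacing_um)
        p <- file.path(out_dir, "quant", paste0(code, "_report.csv"))
        write_report(rep, p)
        per_paths <- c(per_paths, p)
      }
      comb <- combine_reports(per_paths)
      write.csv(comb, file.path(out_dir, "quant/combined.csv"),
                row.names = FALSE)
      write_stage_manifest(out_dir, "quantify", hash_q, q_files, list())
    }
  }
  results$combined <- file.path(out_dir, "quant/combined.csv")

  hash_st <- content_hash(list("stereology", cfg$stereology, cfg$seed, ids))
  st_files <- "stereology/motor_neuron_counts.csv"
  if ("stereology" %in% stages) {
    if (stage_up_to_date(out_dir, "stereology", hash_st)) {
      message("stage stereology: up to date, skipped")
    } else {
      dir.create(file.path(out_dir, "stereology"), showWarnings = FALSE)
      stp <- cfg$stereology
      rows <- lapply(seq_along(ids), function(i) {
        sec <- generate_section_phantom(n_nuclei = stp$n_nuclei,
                                        pixel_spacing_um = stp$pixel_spacing_um,
                                        chat_offset_um = c(1, 8),
                                        seed = cfg$seed + 100L + i)
        det <- detect_double_positive(sec$isl1_labels, sec$chat_mask,
                                      proximity_um = stp$proximity_um,
                                      pixel_spacing_um = stp$pixel_spacing_um)
        motor_neuron_count(code_of[[ids[i]]], det$count, stp$n_sections,
                           stp$thickness_um)
      })
      write.csv(do.call(rbind, rows),
                file.path(out_dir, st_files), row.names = FALSE)
      write_stage_manifest(out_dir, "stereology", hash_st, st_files,
                           cfg$stereology)
    }
  }

  hash_ev <- content_hash(list("evaluate", hash_sim, hash_seg,
                               cfg$evaluation))
  ev_files <- "evaluate/evaluation.json"
  if ("evaluate" %in% stages) {
    require_stage_output(out_dir, "simulate", "evaluate", sim_files)
    require_stage_output(out_dir, "segment", "evaluate", seg_files)
    if (stage_up_to_date(out_dir, "evaluate", hash_ev)) {
      message("stage evaluate: up to date, skipped")
    } else {
      dir.create(file.path(out_dir, "evaluate"), showWarnings = FALSE)
      tp <- fp <- fn <- 0L
      pred_counts <- true_counts <- integer(0)
      for (id in ids) {
        code <- code_of[[id]]
        pred <- read_labels(file.path(out_dir, "seg",
                                      paste0(code, "_neuron_labels.tiff")))
        tru <- read_labels(file.path(out_dir, "sim",
                                     paste0(code, "_truth_neuron.tiff")))
        m <- match_instances(pred, tru, cfg$evaluation$match_iou_min)
        tp <- tp + m[["TP"]]; fp <- fp + m[["FP"]]; fn <- fn + m[["FN"]]
        pred_counts <- c(pred_counts, count_instances(pred))
        true_counts <- c(true_counts, count_instances(tru))
      }
      r2 <- tryCatch(count_correlation(pred_counts, true_counts),
                     error = function(e) NA_real_)
      jsonlite::write_json(
        list(TP = tp, FP = fp, FN = fn, f1 = f1_score(tp, fp, fn),
             count_r2 = r2, match_iou_min = cfg$evaluation$match_iou_min,
             n_stacks = length(ids)),
        file.path(out_dir, ev_files), auto_unbox = TRUE, digits = NA)
      write_stage_manifest(out_dir, "evaluate", hash_ev, ev_files,
                           cfg$evaluation)
    }
  }
  results$evaluation <- file.path(out_dir, ev_files)

  hash_sx <- content_hash(list("stats", hash_q, hash_sim, cfg$stats))
  sx_files <- c("stats/summaries.csv", "stats/fold_changes.csv",
                "stats/neurochem_turnover.csv")
  if ("stats" %in% stages) {
    require_stage_output(out_dir, "quantify", "stats", q_files)
    require_stage_output(out_dir, "simulate", "stats", sim_files)
    if (stage_up_to_date(out_dir, "stats", hash_sx)) {
      message("stage stats: up to date, skipped")
    } else {
      dir.create(file.path(out_dir, "stats"), showWarnings = FALSE)
      comb <- read.csv(file.path(out_dir, "quant/combined.csv"),
                       stringsAsFactors = FALSE)
      bm <- read.csv(file.path(out_dir, "sim/blind_map.csv"),
                     stringsAsFactors = FALSE)
      # un-blind: recover animal id and group from the mapping file
      comb$animal_id <- bm$animal_id[match(comb$stack_id, bm$code)]
      comb$group <- sub("_[0-9]+$", "", comb$animal_id)
      sel <- comb[comb$roi_name == cfg$stats$roi, , drop = FALSE]
      cm <- cohort_metrics(sel, cfg$stats$metric, cfg$stats$reference_group,
                           cfg$stats$remove_outliers)
      write.csv(cm$summaries, file.path(out_dir, "stats/summaries.csv"),
                row.names = FALSE)
      write.csv(cm$fold_changes, file.path(out_dir, "stats/fold_changes.csv"),
                row.names = FALSE)
      nc <- read.csv(file.path(out_dir, "sim/neurochem.csv"),
                     stringsAsFactors = FALSE)
      nc$turnover <- dopamine_turnover(nc$dopamine_ng_per_mg,
                                       nc$dopac_ng_per_mg,
                                       nc$hva_ng_per_mg)
      write.csv(nc, file.path(out_dir, "stats/neurochem_turnover.csv"),
                row.names = FALSE)
      write_stage_manifest(out_dir, "stats", hash_sx, sx_files, cfg$stats)
    }
  }
  results$summaries <- file.path(out_dir, "stats/summaries.csv")
  results$fold_changes <- file.path(out_dir, "stats/fold_changes.csv")
  invisible(results)
}
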