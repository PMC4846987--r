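# Umbrella pipeline: file-based subcommands binding all stages, a strict
# YAML run configuration, and provenance records for every artifact.

pipeline_commands <- c("simulate", "features", "train", "predict",
                       "postprocess", "fuse", "vr-run", "vr-dropout",
                       "evaluate")

default_run_config <- function() {
  list(
    seed = 1L,
    phantom = list(grid_vox = 32L, n_timepoints = 2L, growth_factor = 1.2,
                   noise_sd = 4, bias_amplitude = 0.1, scheme = "gb6"),
    cohort = list(n_patients = 4L, runs_per_rater = 2L,
                  scribble_fraction = 0.05),
    features = list(scales_vox = c(1.0, 3.5), include_t1_subtraction = TRUE),
    forest = list(n_forests = 10L, trees_per_forest = 10L),
    postprocess = list(smoothing_sigma_vox = 1.2, min_component_vox = 1000L,
                       connectivity = 26L),
    pooling = list(max_samples_per_tumor_class = 200L, samples_normal = 1000L),
    dropout = list(keep_probability = 1),
    staple = list(max_iterations = 100L, convergence_tol = 1e-6,
                  init_diag = 0.99999),
    response = list(progression_increase_pct = 25, response_decrease_pct = 50,
                    alt_progression_pct = 40, alt_response_pct = 65)
  )
}

# Merge a user config into the defaults, rejecting unknown keys at both
# levels (strict schema).
merge_config <- function(user, defaults = default_run_config()) {
  bad <- setdiff(names(user), names(defaults))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && !is.null(names(defaults[[nm]]))) {
      badk <- setdiff(names(user[[nm]]), names(defaults[[nm]]))
      if (length(badk))
        stop("unknown config key(s) under '", nm, "': ",
             paste(badk, collapse = ", "))
      defaults[[nm]][names(user[[nm]])] <- user[[nm]]
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

#' Load and validate a YAML run configuration
#'
#' Unknown keys are rejected; omitted keys take the package defaults (the
#' published parameters: sigma 1.2, 1000-voxel components, 10 x 10 trees,
#' scales 1.0/3.5, sampling caps 200/1000, response cutoffs 25/50).
#'
#' @param path YAML file, or `NULL` for pure defaults.
#' @return validated nested configuration list.
#' @export
run_config <- function(path = NULL) {
  if (is.null(path)) return(default_run_config())
  merge_config(yaml::read_yaml(path))
}

config_objects <- function(cfg) {
  scheme <- switch(cfg$phantom$scheme, gb6 = scheme_gb6(),
                   brats5 = scheme_brats5(),
                   stop("unknown scheme: ", cfg$phantom$scheme))
  list(
    scheme = scheme,
    spec = phantom_spec(grid_shape = rep(cfg$phantom$grid_vox, 3),
                        scheme = scheme,
                        n_timepoints = cfg$phantom$n_timepoints,
                        growth_factor = cfg$phantom$growth_factor,
                        noise_sd = cfg$phantom$noise_sd,
                        bias_amplitude = cfg$phantom$bias_amplitude,
                        seed = cfg$seed),
    feat = feature_config(scales_vox = cfg$features$scales_vox,
                          include_t1_subtraction =
                            cfg$features$include_t1_subtraction),
    forest = forest_config(cfg$forest$n_forests, cfg$forest$trees_per_forest,
                           seed = cfg$seed, scheme = scheme),
    post = postprocess_params(cfg$postprocess$smoothing_sigma_vox,
                              cfg$postprocess$min_component_vox,
                              cfg$postprocess$connectivity),
    pool = pooling_config(cfg$pooling$max_samples_per_tumor_class,
                          cfg$pooling$samples_normal, seed = cfg$seed),
    staple = staple_params(cfg$staple$max_iterations,
                           cfg$staple$convergence_tol, cfg$staple$init_diag),
    thresholds = response_thresholds(cfg$response$progression_increase_pct,
                                     cfg$response$response_decrease_pct,
                                     cfg$response$alt_progression_pct,
                                     cfg$response$alt_response_pct)
  )
}

write_provenance <- function(out_path, command, cfg, inputs = character()) {
  prov <- list(
    command = command,
    config_hash = unname(tools::md5sum(textConnectionHash(cfg))),
    seed = cfg$seed,
    software = paste0("virtrater ",
                      as.character(utils::packageVersion("virtrater"))),
    inputs = as.list(stats::setNames(
      unname(tools::md5sum(inputs[file.exists(inputs)])),
      basename(inputs[file.exists(inputs)])))
  )
  jsonlite::write_json(prov, paste0(out_path, ".prov.json"),
                       auto_unbox = TRUE, pretty = TRUE)
}

# md5 of a deparsed config via a temp file (tools::md5sum wants a path).
textConnectionHash <- function(obj) {
  f <- tempfile(fileext = ".txt")
  writeLines(deparse(obj), f)
  f
}

#' Run a pipeline subcommand
#'
#' File-based front end over the package stages.  Supported commands:
#' `simulate` (phantom cohort to a directory), `features` (study NIfTI to
#' feature stack), `postprocess` (probability map to labels), `fuse`
#' (STAPLE over label volumes), `evaluate` (predicted vs reference labels to
#' a metrics CSV), `vr-run` / `vr-dropout` (leave-one-patient-out virtual
#' raters over a cohort directory).  Every written artifact gets a
#' `<file>.prov.json` provenance record (config hash, seed, software
#' version, input hashes).
#'
#' @param command one of the subcommand names.
#' @param args named list of command arguments (paths, rater id, P, force).
#' @param config configuration list from [run_config()].
#' @return command-dependent result, invisibly.
#' @export
run_pipeline <- function(command, args = list(), config = run_config()) {
  command <- match.arg(command, pipeline_commands)
  ob <- config_objects(config)
  res <- switch(
    command,
    "simulate" = {
      raters <- default_rater_pair(config$cohort$scribble_fraction)
      man <- generate_cohort(ob$spec, config$cohort$n_patients, raters,
                             config$cohort$runs_per_rater, out_dir = args$out,
                             force = isTRUE(args$force))
      write_provenance(file.path(args$out, "manifest.csv"), command, config)
      man
    },
    "features" = {
      study <- read_volume(args$study, kind = "image")
      stack <- assemble_feature_stack(study, ob$feat)
      write_volume(stack, args$out)
      write_provenance(args$out, command, config, args$study)
      args$out
    },
    "train" = {
      stack <- read_volume(args$stack, kind = "image")
      scr <- read_scribbles(args$scribbles, ob$scheme, dim(stack))
      ens <- train_forest_ensemble(stack, scr, ob$forest)
      saveRDS(ens, args$out)
      write_provenance(args$out, command, config,
                       c(args$stack, args$scribbles))
      args$out
    },
    "predict" = {
      ens <- readRDS(args$model)
      stack <- read_volume(args$stack, kind = "image")
      probs <- predict_probabilities(ens, stack, ob$scheme)
      write_volume(probs, args$out)
      write_provenance(args$out, command, config, c(args$model, args$stack))
      args$out
    },
    "postprocess" = {
      probs <- read_volume(args$probs, kind = "probs", scheme = ob$scheme)
      seg <- postprocess_segmentation(probs, ob$post)
      write_volume(seg, args$out)
      write_provenance(args$out, command, config, args$probs)
      args$out
    },
    "fuse" = {
      segs <- lapply(args$inputs, read_volume, kind = "labels",
                     scheme = ob$scheme)
      st <- staple_fuse(segs, ob$staple)
      write_volume(st$consensus, args$out)
      if (!is.null(args$theta))
        jsonlite::write_json(lapply(st$theta, as.data.frame), args$theta,
                             pretty = TRUE)
      write_provenance(args$out, command, config, unlist(args$inputs))
      st
    },
    "vr-run" = ,
    "vr-dropout" = {
      cohort <- read_cohort(args$cohort)
      dropout <- if (command == "vr-dropout")
        dropout_config(args$P, seed = config$seed) else NULL
      vr <- run_virtual_rater_lopo(cohort, args$rater,
                                   feat_config = ob$feat,
                                   forest_cfg = ob$forest,
                                   post_params = ob$post,
                                   pool_config = ob$pool,
                                   dropout = dropout)
      dir.create(args$out, showWarnings = FALSE, recursive = TRUE)
      rep <- vr$report |>
        dplyr::select("patient", "timepoint", "rater", "gtv_mm3")
      utils::write.csv(rep, file.path(args$out, "vr_report.csv"),
                       row.names = FALSE)
      for (i in seq_len(nrow(vr$segmentations))) {
        s <- vr$segmentations[i, ]
        write_volume(s$seg[[1]],
                     file.path(args$out, sprintf("vr_%s_p%02d_t%d.nii.gz",
                                                 args$rater, s$patient,
                                                 s$timepoint)))
      }
      write_provenance(file.path(args$out, "vr_report.csv"), command, config)
      vr
    },
    "evaluate" = {
      pred <- read_volume(args$pred, kind = "labels", scheme = ob$scheme)
      ref <- read_volume(args$ref, kind = "labels", scheme = ob$scheme)
      met <- evaluate_segmentation(pred, ref, ob$thresholds)
      utils::write.csv(met, args$out, row.names = FALSE)
      write_provenance(args$out, command, config, c(args$pred, args$ref))
      met
    }
  )
  invisible(res)
}

#' Per-class evaluation of a predicted segmentation against a reference
#'
#' Per-class and GTV Dice plus volumes of both segmentations, and the
#' RANO-style bidimensional product of the predicted enhancing lesion.
#'
#' @param pred,ref [label_volume()]s on the same grid and scheme.
#' @param thresholds a [response_thresholds()] (recorded in the output).
#' @return tibble with one row per class plus a `GTV` row.
#' @export
evaluate_segmentation <- function(pred, ref,
                                  thresholds = response_thresholds()) {
  sch <- pred$scheme
  rows <- lapply(class_ids(sch), function(cid) {
    tibble::tibble(
      class_id = cid, name = class_names(sch)[cid + 1L],
      dice = dice(class_mask(pred, cid), class_mask(ref, cid)),
      volume_pred_mm3 = sum(pred$labels == cid) * prod(pred$voxel_size_mm),
      volume_ref_mm3 = sum(ref$labels == cid) * prod(ref$voxel_size_mm))
  })
  gtv_row <- tibble::tibble(
    class_id = NA_integer_, name = "GTV",
    dice = dice(gtv_mask(pred), gtv_mask(ref)),
    volume_pred_mm3 = gtv_volume(pred),
    volume_ref_mm3 = gtv_volume(ref))
  dplyr::bind_rows(c(rows, list(gtv_row)))
}
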