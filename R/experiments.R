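#' Default pair of simulated raters
#'
#' Two imperfect raters with opposing systematic boundary biases
#' (+0.2 / -0.2 voxels, modeling systematically different inclusion
#' criteria), per-case boundary jitter (sd 0.35 voxels) and a mild
#' edema-versus-normal-tissue confusion at region borders (the classic
#' edema/gliosis ambiguity).  The knobs are calibrated so that pairwise
#' human GTV Dice on the default phantom lands in the mid-0.8 regime
#' typical of human inter-rater agreement on gliomas.
#'
#' @param scribble_fraction fraction of each eroded region emitted as
#'   scribbles (default 0.05).
#' @return named list of two [rater_model()]s (`R1`, `R2`).
#' @export
default_rater_pair <- function(scribble_fraction = 0.05) {
  conf <- list(Edema = c(Rest = 0.2))
  list(
    R1 = rater_model(boundary_bias_vox = 0.2, boundary_jitter_sd = 0.35,
                     confusion = conf, scribble_fraction = scribble_fraction),
    R2 = rater_model(boundary_bias_vox = -0.2, boundary_jitter_sd = 0.35,
                     confusion = conf, scribble_fraction = scribble_fraction)
  )
}

# Pairwise GTV Dice between two sets of dense segmentations of the same
# studies, one row per (patient, timepoint, pair).
pairwise_gtv_dice <- function(segs_a, segs_b, label_a, label_b) {
  purrr::map2_dfr(segs_a, segs_b, function(a, b) {
    tibble::tibble(dice = dice(gtv_mask(a$seg), gtv_mask(b$seg)),
                   patient = a$patient, timepoint = a$timepoint,
                   pair = paste0(label_a, "-", label_b))
  })
}

#' Phantom virtual-rater agreement experiment
#'
#' End-to-end scaled-down emulation of the multi-rater study: simulate a
#' phantom cohort with two noisy raters annotating twice, build the virtual
#' rater of each human rater by leave-one-patient-out pooling, and compare
#' pairwise inter-rater GTV Dice between humans and between virtual raters.
#' Optionally repeats the virtual-rater runs under annotation-instance
#' dropout for a series of keep probabilities P.
#'
#' The post-processing minimum component size defaults to 50 voxels here
#' (not the 1000 of full-resolution clinical grids) because the phantom GTV
#' is only ~1.2k voxels at a 32-voxel grid (clinical GTVs run tens of
#' thousands of mm^3 against the 1000-voxel cutoff); the threshold is scaled
#' to keep the tumor/threshold volume ratio comparable and to stay below the
#' smallest simulated tumor substructure (~130 voxels).
#'
#' @param n_patients number of phantom patients (default 8).
#' @param n_timepoints timepoints per patient (default 2).
#' @param grid_vox isotropic grid side in voxels (default 32).
#' @param seed master seed for the whole experiment.
#' @param raters named list of [rater_model()]s (default
#'   [default_rater_pair()]).
#' @param runs_per_rater annotation runs per rater (default 2).
#' @param dropout_p optional vector of keep probabilities to evaluate
#'   (e.g. `c(1, 0.75, 0.5, 0.25)`).
#' @param post_params [postprocess_params()] for the virtual-rater outputs.
#' @param forest_cfg,pool_config,feat_config classifier, sampling and
#'   feature configurations.
#' @return list with tibbles:
#'   `dice` (`kind` human/vr, `patient`, `timepoint`, `pair`, `dice`),
#'   `gtv` (per source/rater/run GTVs incl. ground truth),
#'   `dropout` (per P: `mean_dice`, `sd_dice`; `NULL` unless requested).
#' @export
vr_agreement_experiment <- function(n_patients = 8L, n_timepoints = 2L,
                                    grid_vox = 32L, seed = 1L,
                                    raters = default_rater_pair(),
                                    runs_per_rater = 2L,
                                    dropout_p = NULL,
                                    post_params =
                                      postprocess_params(min_component_vox = 50L),
                                    forest_cfg = forest_config(seed = seed),
                                    pool_config = pooling_config(seed = seed),
                                    feat_config = feature_config()) {
  spec <- phantom_spec(grid_shape = rep(grid_vox, 3),
                       n_timepoints = n_timepoints, seed = seed)
  cohort <- simulate_cohort(spec, n_patients, raters, runs_per_rater, seed)
  stacks <- cohort_feature_stacks(cohort, feat_config)
  rater_ids <- names(raters)

  ann <- cohort$annotations
  human_rows <- list()
  gtv_rows <- list()
  for (i in seq_len(nrow(cohort$studies))) {
    p <- cohort$studies$patient[i]
    t <- cohort$studies$timepoint[i]
    gtv_rows[[length(gtv_rows) + 1L]] <-
      tibble::tibble(source = "truth", rater = "truth", run = NA_integer_,
                     patient = p, timepoint = t,
                     gtv_mm3 = gtv_volume(cohort$studies$truth[[i]]))
    cell <- ann[ann$patient == p & ann$timepoint == t, ]
    for (j in seq_len(nrow(cell))) {
      gtv_rows[[length(gtv_rows) + 1L]] <-
        tibble::tibble(source = "human", rater = cell$rater[j],
                       run = cell$run[j], patient = p, timepoint = t,
                       gtv_mm3 = gtv_volume(cell$dense[[j]]))
    }
    # inter-rater pairs: every run of one rater vs every run of the other
    for (a in seq_len(nrow(cell))) {
      for (b in seq_len(nrow(cell))) {
        if (a < b && cell$rater[a] != cell$rater[b]) {
          human_rows[[length(human_rows) + 1L]] <- tibble::tibble(
            kind = "human", patient = p, timepoint = t,
            pair = paste0(cell$rater[a], "r", cell$run[a], "-",
                          cell$rater[b], "r", cell$run[b]),
            dice = dice(gtv_mask(cell$dense[[a]]), gtv_mask(cell$dense[[b]])))
        }
      }
    }
  }

  run_vrs <- function(dropout) {
    lapply(rater_ids, function(r)
      run_virtual_rater_lopo(cohort, r, stacks = stacks,
                             feat_config = feat_config,
                             forest_cfg = forest_cfg,
                             post_params = post_params,
                             pool_config = pool_config,
                             dropout = dropout))
  }
  vr_dice_tbl <- function(vrs) {
    out <- list()
    for (a in seq_along(vrs)) {
      for (b in seq_along(vrs)) {
        if (a >= b) next
        sa <- vrs[[a]]$segmentations
        sb <- vrs[[b]]$segmentations
        stopifnot(identical(sa[, c("patient", "timepoint")],
                            sb[, c("patient", "timepoint")]))
        for (i in seq_len(nrow(sa))) {
          out[[length(out) + 1L]] <- tibble::tibble(
            kind = "vr", patient = sa$patient[i], timepoint = sa$timepoint[i],
            pair = paste0(sa$rater[i], "-", sb$rater[i]),
            dice = dice(gtv_mask(sa$seg[[i]]), gtv_mask(sb$seg[[i]])))
        }
      }
    }
    dplyr::bind_rows(out)
  }

  vrs <- run_vrs(NULL)
  vr_dice <- vr_dice_tbl(vrs)
  for (v in vrs) {
    gtv_rows[[length(gtv_rows) + 1L]] <-
      dplyr::mutate(v$report[, c("rater", "patient", "timepoint", "gtv_mm3")],
                    source = "vr", run = NA_integer_)
  }

  dropout_tbl <- NULL
  if (!is.null(dropout_p)) {
    dropout_tbl <- purrr::map_dfr(dropout_p, function(P) {
      vrs_p <- if (P == 1) vrs else
        run_vrs(dropout_config(P, seed = derive_seed(seed, "dropout",
                                                     round(100 * P))))
      dd <- vr_dice_tbl(vrs_p)
      tibble::tibble(P = P, mean_dice = mean(dd$dice), sd_dice = stats::sd(dd$dice),
                     n_pairs = nrow(dd))
    })
  }

  list(
    dice = dplyr::bind_rows(dplyr::bind_rows(human_rows), vr_dice),
    gtv = dplyr::bind_rows(gtv_rows),
    dropout = dropout_tbl,
    vr_reports = lapply(vrs, `[[`, "report")
  )
}

#' Summarise an agreement experiment
#'
#' Mean and standard deviation of pairwise GTV Dice for the human raters and
#' the virtual raters of one experiment run.
#'
#' @param experiment result of [vr_agreement_experiment()].
#' @return tibble with one row per `kind` (`human`, `vr`).
#' @export
summarise_agreement <- function(experiment) {
  experiment$dice |>
    dplyr::group_by(.data$kind) |>
    dplyr::summarise(mean_dice = mean(.data$dice),
                     sd_dice = stats::sd(.data$dice),
                     n_pairs = dplyr::n(), .groups = "drop")
}
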