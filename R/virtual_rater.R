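#' Training-pool sampling caps
#'
#' Caps on the number of training voxels drawn per class: up to
#' `max_samples_per_tumor_class` (default 200) from each tumor-related class
#' and up to `samples_normal` (default 1000) from the background/normal
#' class.  Non-tumor, non-background classes use the tumor cap.
#'
#' @param max_samples_per_tumor_class default 200.
#' @param samples_normal default 1000.
#' @param seed RNG seed for the (without-replacement) sampling.
#' @return an object of class `pooling_config`.
#' @export
pooling_config <- function(max_samples_per_tumor_class = 200L,
                           samples_normal = 1000L, seed = 1L) {
  stopifnot(max_samples_per_tumor_class >= 1L, samples_normal >= 1L)
  structure(
    list(max_samples_per_tumor_class = as.integer(max_samples_per_tumor_class),
         samples_normal = as.integer(samples_normal), seed = as.integer(seed)),
    class = "pooling_config"
  )
}

#' Instance-dropout configuration
#'
#' Each annotation record is independently kept with probability `P`,
#' modeling the realistic case where not every expert annotated every
#' dataset; a dataset losing all records is simply absent from training.
#'
#' @param keep_probability P in (0, 1].
#' @param seed RNG seed.
#' @return an object of class `dropout_config`.
#' @export
dropout_config <- function(keep_probability = 1, seed = 1L) {
  stopifnot(keep_probability > 0, keep_probability <= 1)
  structure(list(keep_probability = keep_probability, seed = as.integer(seed)),
            class = "dropout_config")
}

# Per-class sampling cap given a scheme.
class_cap <- function(class_id, scheme, config) {
  ifelse(class_id == scheme$background_id, config$samples_normal,
         config$max_samples_per_tumor_class)
}

#' Subsample a dense segmentation into training scribbles
#'
#' Converts a dense label volume into a sparse training set by drawing, per
#' class and without replacement, up to 200 voxels from each tumor class and
#' up to 1000 from normal tissue (classes with fewer voxels contribute all
#' of them).  Deterministic given the config seed.
#'
#' @param dense a [label_volume()].
#' @param config a [pooling_config()].
#' @return scribble tibble (`x`, `y`, `z`, `class_id`).
#' @export
subsample_dense_labels <- function(dense, config = pooling_config()) {
  stopifnot(inherits(dense, "label_volume"))
  sch <- dense$scheme
  d <- dim(dense$labels)
  rows <- list()
  for (cid in class_ids(sch)) {
    idx <- which(dense$labels == cid)
    if (!length(idx)) next
    cap <- class_cap(cid, sch, config)
    take <- if (length(idx) > cap) {
      with_seed(derive_seed(config$seed, "densesub", cid), sample(idx, cap))
    } else idx
    co <- arrayInd(take, d)
    rows[[length(rows) + 1L]] <-
      tibble::tibble(x = co[, 1] - 1L, y = co[, 2] - 1L, z = co[, 3] - 1L,
                     class_id = cid)
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "scheme") <- sch
  out
}

#' Apply the per-class caps to a pooled training set
#'
#' Downsamples a pooled multi-study scribble table so each class keeps at
#' most its cap (tumor classes 200, background 1000 by default), sampling
#' without replacement across all contributing records.
#'
#' @param pool pooled scribble tibble (may carry study columns).
#' @param scheme a [label_scheme()].
#' @param config a [pooling_config()].
#' @return the downsampled tibble.
#' @export
subsample_training_pool <- function(pool, scheme, config = pooling_config()) {
  keep <- unlist(lapply(split(seq_len(nrow(pool)), pool$class_id),
                        function(ix) {
    cid <- pool$class_id[ix[1]]
    cap <- class_cap(cid, scheme, config)
    if (length(ix) > cap)
      with_seed(derive_seed(config$seed, "poolsub", cid), sample(ix, cap))
    else ix
  }), use.names = FALSE)
  pool[sort(keep), ]
}

#' Assemble the virtual-rater training pool
#'
#' The virtual-rater protocol: pool ALL raters' and runs' annotations on
#' every patient except the held-out one, together with only the current
#' rater's annotations (all their runs) on the held-out patient.  Every
#' scribble keeps its (patient, timepoint, rater, run) provenance so feature
#' vectors are extracted from the correct study.
#'
#' @param cohort a `vr_cohort`.
#' @param held_out_patient patient id held out of historical training.
#' @param current_rater rater id whose annotations of the held-out patient
#'   join the pool (the instantaneous rating; required).
#' @param kind `"sparse"` (default; uses the scribble records) or `"dense"`
#'   (subsamples the dense records via [subsample_dense_labels()]).
#' @param config [pooling_config()] used when `kind = "dense"`.
#' @return tibble with columns `patient`, `timepoint`, `rater`, `run`, `x`,
#'   `y`, `z`, `class_id`.
#' @export
assemble_training_pool <- function(cohort, held_out_patient, current_rater,
                                   kind = c("sparse", "dense"),
                                   config = pooling_config()) {
  kind <- match.arg(kind)
  ann <- cohort$annotations
  if (!held_out_patient %in% cohort$studies$patient)
    stop("unknown held-out patient: ", held_out_patient)
  if (!any(ann$patient != held_out_patient))
    stop("single-patient cohort: no historical patients to train from")
  sel <- ann$patient != held_out_patient |
    (ann$patient == held_out_patient & ann$rater == current_rater)
  cur <- ann$patient == held_out_patient & ann$rater == current_rater
  if (!any(cur))
    stop("rater ", current_rater, " has no annotation on held-out patient ",
         held_out_patient, " (the virtual rater requires the instantaneous rating)")
  ann <- ann[sel, ]
  rows <- lapply(seq_len(nrow(ann)), function(i) {
    scr <- if (kind == "sparse") ann$scribbles[[i]] else {
      cfg <- config
      cfg$seed <- derive_seed(config$seed, "record", ann$patient[i],
                              ann$timepoint[i], ann$rater[i], ann$run[i])
      subsample_dense_labels(ann$dense[[i]], cfg)
    }
    if (!nrow(scr)) return(NULL)
    dplyr::mutate(scr, patient = ann$patient[i], timepoint = ann$timepoint[i],
                  rater = ann$rater[i], run = ann$run[i],
                  .before = 1L)
  })
  dplyr::bind_rows(rows)
}

#' Drop annotation records with probability 1 - P
#'
#' Keeps each record of a table independently with probability
#' `keep_probability`; deterministic given the config seed.  With P = 1 the
#' table is returned unchanged.
#'
#' @param records tibble (or data frame) of annotation records.
#' @param config a [dropout_config()].
#' @return the surviving rows.
#' @export
dropout_segmentations <- function(records, config) {
  stopifnot(inherits(config, "dropout_config"))
  if (config$keep_probability == 1) return(records)
  keep <- with_seed(derive_seed(config$seed, "dropout"),
                    stats::runif(nrow(records)) < config$keep_probability)
  records[keep, , drop = FALSE]
}

# Feature stacks for every study of a cohort, keyed "patient.timepoint".
study_key <- function(patient, timepoint) paste0(patient, ".", timepoint)

#' Precompute feature stacks for all studies of a cohort
#'
#' @param cohort a `vr_cohort`.
#' @param feat_config a [feature_config()].
#' @return named list of feature-stack [mc_volume()]s keyed
#'   `"<patient>.<timepoint>"`.
#' @export
cohort_feature_stacks <- function(cohort, feat_config = feature_config()) {
  stacks <- lapply(seq_len(nrow(cohort$studies)), function(i)
    assemble_feature_stack(cohort$studies$image[[i]], feat_config))
  names(stacks) <- study_key(cohort$studies$patient, cohort$studies$timepoint)
  stacks
}

# Feature matrix + labels for a pooled scribble table.
pool_training_matrix <- function(pool, stacks) {
  parts <- lapply(split(seq_len(nrow(pool)),
                        study_key(pool$patient, pool$timepoint)),
                  function(ix) {
    key <- study_key(pool$patient[ix[1]], pool$timepoint[ix[1]])
    features_at(stacks[[key]], as.matrix(pool[ix, c("x", "y", "z")]))
  })
  x <- do.call(rbind, parts)
  y <- unlist(lapply(split(pool$class_id,
                           study_key(pool$patient, pool$timepoint)),
                     identity), use.names = FALSE)
  list(x = x, y = y)
}

#' Run the virtual rater with leave-one-patient-out training
#'
#' For every patient: assemble the training pool (all raters' historical
#' annotations plus the current rater's annotations of the held-out
#' patient), optionally drop historical records with probability `1 - P`,
#' apply the per-class sampling caps, train the merged random-forest
#' ensemble, predict every timepoint of the held-out patient and
#' post-process.  One virtual rater per human rater.
#'
#' @param cohort a `vr_cohort`.
#' @param rater_id the human rater the virtual rater accompanies.
#' @param stacks precomputed [cohort_feature_stacks()] (computed on the fly
#'   if `NULL`).
#' @param feat_config [feature_config()].
#' @param forest_cfg [forest_config()] (its scheme is forced to the cohort's).
#' @param post_params [postprocess_params()].
#' @param pool_config [pooling_config()].
#' @param dropout [dropout_config()] applied to historical records only
#'   (the current rater's held-out annotations always stay), or `NULL`.
#' @param kind `"sparse"` or `"dense"` annotation payloads (see
#'   [assemble_training_pool()]).
#' @return list with `segmentations` (tibble `patient`, `timepoint`,
#'   `rater`, list-column `seg`) and `report` (one row per patient and
#'   timepoint: GTV, per-class volumes nested in `volumes`).
#' @export
run_virtual_rater_lopo <- function(cohort, rater_id, stacks = NULL,
                                   feat_config = feature_config(),
                                   forest_cfg = forest_config(),
                                   post_params = postprocess_params(),
                                   pool_config = pooling_config(),
                                   dropout = NULL,
                                   kind = "sparse") {
  if (is.null(stacks)) stacks <- cohort_feature_stacks(cohort, feat_config)
  forest_cfg$scheme <- cohort$scheme
  patients <- sort(unique(cohort$studies$patient))
  seg_rows <- list()
  rep_rows <- list()
  for (p in patients) {
    coh_p <- cohort
    if (!is.null(dropout)) {
      ann <- cohort$annotations
      hist <- ann[ann$patient != p, ]
      cfg <- dropout
      cfg$seed <- derive_seed(dropout$seed, "patient", p)
      hist <- dropout_segmentations(hist, cfg)
      cur <- ann[ann$patient == p & ann$rater == rater_id, ]
      coh_p$annotations <- dplyr::bind_rows(hist, cur)
    }
    pool <- tryCatch(
      assemble_training_pool(coh_p, p, rater_id, kind = kind,
                             config = pool_config),
      error = function(e) stop("patient ", p, ": ", conditionMessage(e)))
    pool <- subsample_training_pool(pool, cohort$scheme, pool_config)
    tm <- pool_training_matrix(pool, stacks)
    cfg <- forest_cfg
    cfg$seed <- derive_seed(forest_cfg$seed, "vr", rater_id, p)
    ens <- train_forest_matrix(tm$x, tm$y, cfg)
    tps <- cohort$studies[cohort$studies$patient == p, ]
    for (i in seq_len(nrow(tps))) {
      t <- tps$timepoint[i]
      probs <- predict_probabilities(ens, stacks[[study_key(p, t)]],
                                     cohort$scheme)
      seg <- postprocess_segmentation(probs, post_params)
      vols <- class_volumes(seg)
      seg_rows[[length(seg_rows) + 1L]] <-
        tibble::tibble(patient = p, timepoint = t,
                       rater = paste0("VR_", rater_id), seg = list(seg))
      rep_rows[[length(rep_rows) + 1L]] <-
        tibble::tibble(patient = p, timepoint = t,
                       rater = paste0("VR_", rater_id),
                       gtv_mm3 = attr(vols, "gtv_mm3"),
                       volumes = list(vols))
    }
  }
  list(segmentations = dplyr::bind_rows(seg_rows),
       report = dplyr::bind_rows(rep_rows))
}
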