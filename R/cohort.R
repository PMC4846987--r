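#' Simulate a multi-rater phantom cohort in memory
#'
#' Generates `n_patients` longitudinal phantom studies (per-patient tumor
#' geometry jittered around the spec) and, for every study, each simulated
#' rater's dense segmentation and sparse scribbles for `runs_per_rater`
#' independent runs.  Every (patient, timepoint, rater, run) cell draws its
#' RNG stream from a sub-seed of `seed`, so cohorts are stable under partial
#' regeneration.
#'
#' @param spec a [phantom_spec()] (base geometry; per-patient centers and
#'   radii are jittered deterministically).
#' @param n_patients number of patients (>= 2 so leave-one-out has training
#'   data).
#' @param raters list of [rater_model()]s; names become rater ids (default
#'   `R1`, `R2`, ...).  May be empty (images only).
#' @param runs_per_rater repeated annotation runs per rater (default 2).
#' @param seed master seed (default: the spec's).
#' @return an object of class `vr_cohort` with tibbles `studies` (`patient`,
#'   `timepoint`, list-columns `image`, `truth`) and `annotations`
#'   (`patient`, `timepoint`, `rater`, `run`, list-columns `dense`,
#'   `scribbles`).
#' @export
simulate_cohort <- function(spec, n_patients, raters = list(),
                            runs_per_rater = 2L, seed = spec$seed) {
  stopifnot(inherits(spec, "phantom_spec"), n_patients >= 2L)
  if (length(raters) && is.null(names(raters)))
    names(raters) <- paste0("R", seq_along(raters))
  studies <- list()
  anns <- list()
  for (p in seq_len(n_patients)) {
    pseed <- derive_seed(seed, "patient", p)
    jit <- with_seed(pseed, list(center = stats::runif(3, -1.5, 1.5),
                                 rscale = stats::runif(1, 0.9, 1.05)))
    pspec <- spec
    pspec$tumor_center <- spec$tumor_center + jit$center
    pspec$tumor_radii <- spec$tumor_radii * jit$rscale
    pspec$seed <- pseed
    for (t in 0:(spec$n_timepoints - 1L)) {
      ph <- generate_phantom(pspec, t)
      studies[[length(studies) + 1L]] <-
        tibble::tibble(patient = p, timepoint = t,
                       image = list(ph$image), truth = list(ph$truth))
      for (ri in seq_along(raters)) {
        for (k in seq_len(runs_per_rater)) {
          model <- raters[[ri]]
          model$seed <- derive_seed(seed, "ann", p, t, ri, k)
          dense <- simulate_rater(ph$truth, model)
          scr <- withCallingHandlers(
            extract_scribbles(dense, model),
            virtrater_empty_scribbles = function(c) invokeRestart("muffleMessage")
          )
          anns[[length(anns) + 1L]] <-
            tibble::tibble(patient = p, timepoint = t,
                           rater = names(raters)[ri], run = k,
                           dense = list(dense), scribbles = list(scr))
        }
      }
    }
  }
  structure(
    list(
      spec = spec, seed = as.integer(seed), scheme = spec$scheme,
      studies = dplyr::bind_rows(studies),
      annotations = if (length(anns)) dplyr::bind_rows(anns) else
        tibble::tibble(patient = integer(), timepoint = integer(),
                       rater = character(), run = integer(),
                       dense = list(), scribbles = list())
    ),
    class = "vr_cohort"
  )
}

#' @export
print.vr_cohort <- function(x, ...) {
  cat("<vr_cohort> ", dplyr::n_distinct(x$studies$patient), " patients x ",
      dplyr::n_distinct(x$studies$timepoint), " timepoints; ",
      nrow(x$annotations), " annotation record(s) from ",
      dplyr::n_distinct(x$annotations$rater), " rater(s)\n", sep = "")
  invisible(x)
}

#' Write a simulated cohort to disk
#'
#' Writes per-study 4D NIfTI images (channel order nT1w, ceT1w, T2w, FLAIR,
#' recorded in a JSON sidecar), ground-truth and per-rater dense label
#' volumes as NIfTI, scribbles both as CSV (`x,y,z,class_id`, 0-based voxel
#' indices; the canonical form) and as a sparse NIfTI label volume (class id
#' + 1, 0 = unlabeled), plus a `manifest.csv` tying everything together.
#'
#' @param cohort a [simulate_cohort()] result.
#' @param out_dir output directory.
#' @param force overwrite an existing non-empty directory (default FALSE:
#'   refuse).
#' @return the manifest tibble (`patient`, `timepoint`, `rater`, `run`,
#'   `kind`, `path`), invisibly.
#' @export
write_cohort <- function(cohort, out_dir, force = FALSE) {
  stopifnot(inherits(cohort, "vr_cohort"))
  if (dir.exists(out_dir) && length(dir(out_dir)) && !force)
    stop("output directory ", out_dir, " exists and is not empty; ",
         "use force = TRUE to overwrite")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list()
  add <- function(patient, timepoint, rater, run, kind, path) {
    rows[[length(rows) + 1L]] <<-
      tibble::tibble(patient = patient, timepoint = timepoint,
                     rater = rater, run = run, kind = kind, path = path)
  }
  for (i in seq_len(nrow(cohort$studies))) {
    st <- cohort$studies[i, ]
    stem <- sprintf("p%02d_t%d", st$patient, st$timepoint)
    img_path <- file.path(out_dir, paste0(stem, "_image.nii.gz"))
    write_volume(st$image[[1]], img_path)
    add(st$patient, st$timepoint, NA_character_, NA_integer_, "image",
        basename(img_path))
    tr_path <- file.path(out_dir, paste0(stem, "_truth.nii.gz"))
    write_volume(st$truth[[1]], tr_path)
    add(st$patient, st$timepoint, NA_character_, NA_integer_, "truth",
        basename(tr_path))
  }
  for (i in seq_len(nrow(cohort$annotations))) {
    an <- cohort$annotations[i, ]
    stem <- sprintf("p%02d_t%d_%s_run%d", an$patient, an$timepoint,
                    an$rater, an$run)
    dn_path <- file.path(out_dir, paste0(stem, "_dense.nii.gz"))
    write_volume(an$dense[[1]], dn_path)
    add(an$patient, an$timepoint, an$rater, an$run, "dense", basename(dn_path))
    sc_path <- file.path(out_dir, paste0(stem, "_scribbles.csv"))
    write_scribbles(an$scribbles[[1]], sc_path)
    add(an$patient, an$timepoint, an$rater, an$run, "scribbles",
        basename(sc_path))
    sn_path <- file.path(out_dir, paste0(stem, "_scribbles.nii.gz"))
    write_volume(scribbles_to_sparse_volume(an$scribbles[[1]],
                                            dim(an$dense[[1]]),
                                            an$dense[[1]]$voxel_size_mm),
                 sn_path, raw_array = TRUE)
    add(an$patient, an$timepoint, an$rater, an$run, "scribbles_nifti",
        basename(sn_path))
  }
  manifest <- dplyr::bind_rows(rows)
  utils::write.csv(manifest, file.path(out_dir, "manifest.csv"),
                   row.names = FALSE)
  invisible(manifest)
}

#' @rdname write_cohort
#' @param spec,n_patients,raters,runs_per_rater,seed passed to
#'   [simulate_cohort()].
#' @export
generate_cohort <- function(spec, n_patients, raters = list(),
                            runs_per_rater = 2L, out_dir, force = FALSE,
                            seed = spec$seed) {
  cohort <- simulate_cohort(spec, n_patients, raters, runs_per_rater, seed)
  write_cohort(cohort, out_dir, force)
}

# Sparse scribble volume: class_id + 1 at scribble voxels, 0 elsewhere.
scribbles_to_sparse_volume <- function(scribbles, dims, voxel_size_mm) {
  v <- array(0L, dims)
  if (nrow(scribbles)) {
    lin <- 1L + scribbles$x + dims[1] * (scribbles$y + dims[2] * scribbles$z)
    v[lin] <- scribbles$class_id + 1L
  }
  list(array = v, voxel_size_mm = voxel_size_mm)
}
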