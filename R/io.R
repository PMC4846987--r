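# NIfTI, CSV and config I/O.  Conventions: 0-based voxel indices everywhere;
# voxel spacing travels in the NIfTI pixdim; channel/class names travel in a
# JSON sidecar (<file>.json) because NIfTI-1 has no channel names.

sidecar_path <- function(path) sub("\\.nii(\\.gz)?$", ".json", path)

as_nifti_with_spacing <- function(arr, voxel_size_mm) {
  nd <- length(dim(arr))
  img <- RNifti::asNifti(arr)
  pd <- RNifti::pixdim(img)
  pd[1:3] <- voxel_size_mm
  RNifti::pixdim(img) <- pd[seq_len(min(nd, length(pd)))]
  img
}

#' Write a volume to NIfTI
#'
#' Multi-channel volumes and probability maps are written as 4D NIfTI with a
#' JSON sidecar recording the channel (or class) names and order; label
#' volumes as 3D integer NIfTI.
#'
#' @param x an [mc_volume()], [label_volume()], [prob_map()] or a
#'   `list(array =, voxel_size_mm =)`.
#' @param path output path (`.nii` or `.nii.gz`).
#' @param raw_array internal: treat `x` as a bare array wrapper.
#' @return `path`, invisibly.
#' @export
write_volume <- function(x, path, raw_array = FALSE) {
  if (raw_array || (is.list(x) && !is.null(x$array))) {
    RNifti::writeNifti(as_nifti_with_spacing(x$array, x$voxel_size_mm), path)
  } else if (inherits(x, "mc_volume")) {
    arr <- array(unlist(x$channels, use.names = FALSE),
                 c(dim(x), length(x$channels)))
    RNifti::writeNifti(as_nifti_with_spacing(arr, x$voxel_size_mm), path)
    jsonlite::write_json(list(kind = "image", channels = channel_names(x)),
                         sidecar_path(path), auto_unbox = TRUE)
  } else if (inherits(x, "label_volume")) {
    RNifti::writeNifti(as_nifti_with_spacing(x$labels, x$voxel_size_mm), path,
                       datatype = "int16")
    jsonlite::write_json(
      list(kind = "labels", classes = class_names(x$scheme),
           tumor_class_ids = x$scheme$tumor_class_ids,
           background_id = x$scheme$background_id),
      sidecar_path(path), auto_unbox = TRUE)
  } else if (inherits(x, "prob_map")) {
    RNifti::writeNifti(as_nifti_with_spacing(x$probs, x$voxel_size_mm), path)
    jsonlite::write_json(
      list(kind = "probs", classes = class_names(x$scheme),
           tumor_class_ids = x$scheme$tumor_class_ids,
           background_id = x$scheme$background_id),
      sidecar_path(path), auto_unbox = TRUE)
  } else {
    stop("don't know how to write object of class ", paste(class(x), collapse = "/"))
  }
  invisible(path)
}

scheme_from_sidecar <- function(meta) {
  label_scheme(unlist(meta$classes),
               tumor_classes = unlist(meta$tumor_class_ids),
               background = meta$background_id)
}

#' Read a volume from NIfTI
#'
#' Uses the JSON sidecar (if present) to restore channel names and label
#' schemes.  Label volumes are validated to be integer-valued.
#'
#' @param path NIfTI file.
#' @param kind `"auto"` (default, from the sidecar), `"image"`, `"labels"`
#'   or `"probs"`.
#' @param scheme [label_scheme()] for label/probability volumes without a
#'   sidecar.
#' @return an [mc_volume()], [label_volume()] or [prob_map()].
#' @export
read_volume <- function(path, kind = "auto", scheme = NULL) {
  img <- RNifti::readNifti(path)
  spacing <- RNifti::pixdim(img)[1:3]
  arr <- array(as.vector(img), dim(img)) # strip NIfTI attributes
  meta <- NULL
  sp <- sidecar_path(path)
  if (file.exists(sp)) meta <- jsonlite::read_json(sp)
  if (kind == "auto") kind <- if (!is.null(meta)) meta$kind
    else if (length(dim(arr)) == 3L) "labels" else "image"
  if (kind == "image") {
    d <- dim(arr)
    if (length(d) == 3L) arr <- array(arr, c(d, 1L))
    nch <- dim(arr)[4]
    nms <- if (!is.null(meta)) unlist(meta$channels) else paste0("ch", seq_len(nch))
    chans <- stats::setNames(
      lapply(seq_len(nch), function(i) arr[, , , i, drop = TRUE]), nms)
    chans <- lapply(chans, function(a) array(a, dim(arr)[1:3]))
    mc_volume(chans, spacing)
  } else if (kind == "labels") {
    if (length(dim(arr)) != 3L) stop("label volume must be 3D")
    if (any(arr != round(arr)))
      stop("label volume contains non-integer values (e.g. ",
           arr[which(arr != round(arr))[1]], ")")
    if (is.null(scheme)) {
      if (is.null(meta)) stop("no sidecar and no scheme given for label volume")
      scheme <- scheme_from_sidecar(meta)
    }
    label_volume(array(as.integer(round(arr)), dim(arr)), scheme, spacing)
  } else if (kind == "probs") {
    if (length(dim(arr)) != 4L) stop("probability map must be 4D")
    if (is.null(scheme)) {
      if (is.null(meta)) stop("no sidecar and no scheme given for probability map")
      scheme <- scheme_from_sidecar(meta)
    }
    prob_map(arr, scheme, spacing)
  } else stop("unknown kind: ", kind)
}

#' Write scribbles to CSV
#'
#' Canonical sparse annotation format: header `x,y,z,class_id`, 0-based voxel
#' indices with x the fastest-varying axis of the stored array.
#'
#' @param scribbles scribble tibble.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_scribbles <- function(scribbles, path) {
  utils::write.csv(scribbles[, c("x", "y", "z", "class_id")], path,
                   row.names = FALSE)
  invisible(path)
}

#' Read scribbles from CSV
#'
#' Parses and validates a `x,y,z,class_id` table: class ids must belong to
#' the scheme (errors carry the offending line number), and a voxel listed
#' twice with conflicting classes is an error.
#'
#' @param path CSV path.
#' @param scheme a [label_scheme()].
#' @param dims optional grid dimensions for bounds checking.
#' @return scribble tibble with attribute `scheme`.
#' @export
read_scribbles <- function(path, scheme, dims = NULL) {
  df <- utils::read.csv(path)
  need <- c("x", "y", "z", "class_id")
  if (!identical(names(df)[seq_len(4)], need))
    stop("scribble CSV must have header x,y,z,class_id")
  bad <- which(!(df$class_id %in% class_ids(scheme)))
  if (length(bad))
    stop("class id ", df$class_id[bad[1]], " outside the scheme at line ",
         bad[1] + 1L) # +1 for the header line
  if (!is.null(dims)) {
    oob <- which(df$x < 0 | df$y < 0 | df$z < 0 |
                 df$x >= dims[1] | df$y >= dims[2] | df$z >= dims[3])
    if (length(oob))
      stop("scribble out of bounds at line ", oob[1] + 1L)
  }
  key <- paste(df$x, df$y, df$z)
  dup <- duplicated(key)
  if (any(dup)) {
    first_class <- df$class_id[match(key, key)]
    conflict <- which(dup & df$class_id != first_class)
    if (length(conflict))
      stop("conflicting duplicate scribble at line ", conflict[1] + 1L)
    df <- df[!dup, ]
  }
  out <- tibble::as_tibble(df[, need])
  attr(out, "scheme") <- scheme
  out
}

#' Read a cohort manifest
#'
#' @param path manifest CSV written by [write_cohort()] (or the directory
#'   containing `manifest.csv`).
#' @return manifest tibble with absolute paths in a `path_abs` column.
#' @export
read_manifest <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "manifest.csv")
  m <- tibble::as_tibble(utils::read.csv(path))
  miss <- !file.exists(file.path(dirname(path), m$path))
  if (any(miss))
    stop("manifest references missing file(s): ",
         paste(utils::head(m$path[miss], 3), collapse = ", "))
  m$path_abs <- file.path(normalizePath(dirname(path)), m$path)
  m
}

#' Load a written cohort back into memory
#'
#' Inverse of [write_cohort()]: reconstructs the `vr_cohort` study and
#' annotation tables from a manifest directory.
#'
#' @param dir cohort directory containing `manifest.csv`.
#' @return a `vr_cohort` (without the originating `phantom_spec`).
#' @export
read_cohort <- function(dir) {
  m <- read_manifest(dir)
  scheme <- NULL
  studies <- m |>
    dplyr::filter(.data$kind %in% c("image", "truth")) |>
    dplyr::group_by(.data$patient, .data$timepoint) |>
    dplyr::group_map(function(g, key) {
      img <- read_volume(g$path_abs[g$kind == "image"][1])
      tr <- read_volume(g$path_abs[g$kind == "truth"][1])
      scheme <<- tr$scheme
      tibble::tibble(patient = key$patient, timepoint = key$timepoint,
                     image = list(img), truth = list(tr))
    }) |>
    dplyr::bind_rows()
  ann_rows <- m |> dplyr::filter(.data$kind %in% c("dense", "scribbles"))
  annotations <- if (nrow(ann_rows)) {
    ann_rows |>
      dplyr::group_by(.data$patient, .data$timepoint, .data$rater, .data$run) |>
      dplyr::group_map(function(g, key) {
        dense <- read_volume(g$path_abs[g$kind == "dense"][1])
        scr <- read_scribbles(g$path_abs[g$kind == "scribbles"][1],
                              dense$scheme, dim(dense))
        tibble::tibble(patient = key$patient, timepoint = key$timepoint,
                       rater = key$rater, run = key$run,
                       dense = list(dense), scribbles = list(scr))
      }) |>
      dplyr::bind_rows()
  } else {
    tibble::tibble(patient = integer(), timepoint = integer(),
                   rater = character(), run = integer(),
                   dense = list(), scribbles = list())
  }
  structure(list(spec = NULL, seed = NA_integer_, scheme = scheme,
                 studies = studies, annotations = annotations),
            class = "vr_cohort")
}
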