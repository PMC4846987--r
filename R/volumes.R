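#' Multi-channel volume container
#'
#' A light container for a co-registered multi-channel 3D study: a named list
#' of equally-shaped 3D arrays (raw MRI modalities or computed features) plus
#' the voxel spacing in mm.
#'
#' @param channels named list of 3D numeric arrays with identical dimensions.
#' @param voxel_size_mm numeric length-3 spacing in mm (default 1 mm isotropic).
#' @return an object of class `mc_volume`.
#' @export
mc_volume <- function(channels, voxel_size_mm = c(1, 1, 1)) {
  stopifnot(is.list(channels), length(channels) >= 1L,
            !is.null(names(channels)), all(nzchar(names(channels))))
  dims <- dim(channels[[1]])
  stopifnot(length(dims) == 3L)
  for (nm in names(channels)) {
    if (!identical(dim(channels[[nm]]), dims))
      stop("channel '", nm, "' has mismatching dimensions")
  }
  structure(
    list(channels = channels, voxel_size_mm = as.numeric(voxel_size_mm)),
    class = "mc_volume"
  )
}

#' @export
print.mc_volume <- function(x, ...) {
  cat("<mc_volume> ", paste(dim(x$channels[[1]]), collapse = "x"),
      " voxels, ", length(x$channels), " channel(s): ",
      paste(utils::head(names(x$channels), 8), collapse = ", "),
      if (length(x$channels) > 8) ", ..." else "", "\n", sep = "")
  invisible(x)
}

#' @export
dim.mc_volume <- function(x) dim(x$channels[[1]])

channel_names <- function(x) names(x$channels)

#' Dense label volume container
#'
#' @param labels 3D integer array of class ids.
#' @param scheme a [label_scheme()] whose ids the labels must use.
#' @param voxel_size_mm spacing in mm.
#' @return an object of class `label_volume`.
#' @export
label_volume <- function(labels, scheme, voxel_size_mm = c(1, 1, 1)) {
  stopifnot(length(dim(labels)) == 3L, inherits(scheme, "label_scheme"))
  if (is.double(labels)) {
    if (any(labels != round(labels))) stop("labels must be integer-valued")
    storage.mode(labels) <- "integer"
  }
  bad <- setdiff(unique(as.vector(labels)), class_ids(scheme))
  if (length(bad)) stop("labels contain ids outside the scheme: ",
                        paste(bad, collapse = ", "))
  structure(
    list(labels = labels, scheme = scheme,
         voxel_size_mm = as.numeric(voxel_size_mm)),
    class = "label_volume"
  )
}

#' @export
print.label_volume <- function(x, ...) {
  tab <- table(factor(as.vector(x$labels), levels = class_ids(x$scheme)))
  cat("<label_volume> ", paste(dim(x$labels), collapse = "x"), " voxels; ",
      paste(sprintf("%s=%d", class_names(x$scheme), as.integer(tab)),
            collapse = " "), "\n", sep = "")
  invisible(x)
}

#' @export
dim.label_volume <- function(x) dim(x$labels)

#' Per-class probability map container
#'
#' Holds one pseudo-probability grid per class of a scheme, stored as a 4D
#' array `[x, y, z, class]`.  Voxelwise values are non-negative and sum to 1.
#'
#' @param probs 4D array with one slab per scheme class (scheme id order).
#' @param scheme a [label_scheme()].
#' @param voxel_size_mm spacing in mm.
#' @param check validate non-negativity and normalization (default TRUE).
#' @return an object of class `prob_map`.
#' @export
prob_map <- function(probs, scheme, voxel_size_mm = c(1, 1, 1), check = TRUE) {
  stopifnot(length(dim(probs)) == 4L, inherits(scheme, "label_scheme"),
            dim(probs)[4] == n_classes(scheme))
  if (check) {
    if (any(probs < -1e-9)) stop("negative probabilities")
    s <- rowSums(matrix(probs, ncol = dim(probs)[4]))
    if (max(abs(s - 1)) > 1e-6) stop("probabilities do not sum to 1 (max dev ",
                                     signif(max(abs(s - 1)), 3), ")")
  }
  structure(
    list(probs = probs, scheme = scheme, voxel_size_mm = as.numeric(voxel_size_mm)),
    class = "prob_map"
  )
}

#' @export
print.prob_map <- function(x, ...) {
  cat("<prob_map> ", paste(dim(x$probs)[1:3], collapse = "x"), " voxels, ",
      dim(x$probs)[4], " classes\n", sep = "")
  invisible(x)
}

#' @export
dim.prob_map <- function(x) dim(x$probs)[1:3]

# Binary mask of one class (or the merged GTV) from a label volume.
class_mask <- function(lab, class_id) {
  array(lab$labels %in% class_id, dim = dim(lab$labels))
}

#' Merged gross-tumor-volume mask
#'
#' Merges all tumor-related classes of the volume's scheme into one binary
#' mask (the GTV).
#'
#' @param lab a [label_volume()].
#' @return logical 3D array.
#' @export
gtv_mask <- function(lab) {
  class_mask(lab, lab$scheme$tumor_class_ids)
}
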