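#' Post-processing parameters
#'
#' The fixed chain applied to classifier pseudo-probabilities: Gaussian
#' smoothing of each class channel (sigma = 1.2 voxels), voxelwise argmax
#' (ties to the lowest class id), and removal of connected components smaller
#' than 1000 voxels (strictly smaller; an exactly-1000-voxel component
#' survives).
#'
#' @param smoothing_sigma_vox Gaussian sigma in voxels (default 1.2; 0 = off).
#' @param min_component_vox minimum surviving component size in voxels
#'   (default 1000; 0 = off).  Defaults suit 1 mm isotropic clinical volumes;
#'   scale it with the grid for small phantoms.
#' @param connectivity 26 (default) or 6.
#' @param filter_scope `"per_class"` (default): components of each
#'   non-background class are measured independently; `"foreground"`:
#'   components of the merged non-background mask.
#' @param removed_to id the removed components are reassigned to; `NULL`
#'   (default) = the scheme's background class.
#' @return an object of class `postprocess_params`.
#' @export
postprocess_params <- function(smoothing_sigma_vox = 1.2,
                               min_component_vox = 1000L,
                               connectivity = 26L,
                               filter_scope = c("per_class", "foreground"),
                               removed_to = NULL) {
  stopifnot(smoothing_sigma_vox >= 0, min_component_vox >= 0,
            connectivity %in% c(6L, 26L))
  structure(
    list(smoothing_sigma_vox = smoothing_sigma_vox,
         min_component_vox = as.integer(min_component_vox),
         connectivity = as.integer(connectivity),
         filter_scope = match.arg(filter_scope),
         removed_to = removed_to),
    class = "postprocess_params"
  )
}

#' Smooth a probability map channelwise
#'
#' Applies the same Gaussian kernel to every class channel (symmetric-reflect
#' boundaries).  Smoothing is linear and preserves constants, so voxelwise
#' sums remain 1.
#'
#' @param probs a [prob_map()].
#' @param params a [postprocess_params()].
#' @return a smoothed [prob_map()].
#' @export
smooth_probabilities <- function(probs, params = postprocess_params()) {
  stopifnot(inherits(probs, "prob_map"))
  s <- params$smoothing_sigma_vox
  if (s == 0) return(probs)
  out <- probs$probs
  for (k in seq_len(dim(out)[4])) {
    out[, , , k] <- gaussian_smooth3(out[, , , k], s)
  }
  prob_map(out, probs$scheme, probs$voxel_size_mm)
}

#' Argmax labels of a probability map
#'
#' Per voxel, the class with maximal probability; exact ties go to the lowest
#' class id.
#'
#' @param probs a [prob_map()].
#' @param params a [postprocess_params()] (unused fields ignored).
#' @return a [label_volume()].
#' @export
argmax_labels <- function(probs, params = postprocess_params()) {
  stopifnot(inherits(probs, "prob_map"))
  d <- dim(probs$probs)
  m <- matrix(probs$probs, prod(d[1:3]), d[4])
  # max.col(ties.method = "first") = lowest class id on exact ties
  lab <- max.col(m, ties.method = "first") - 1L
  label_volume(array(lab, d[1:3]), probs$scheme, probs$voxel_size_mm)
}

#' Remove small connected components
#'
#' For every non-background class (or for the merged foreground, per
#' `filter_scope`), connected components with fewer than `min_component_vox`
#' voxels are reassigned to the background class; components at or above the
#' threshold are untouched.
#'
#' @param labels a [label_volume()].
#' @param params a [postprocess_params()].
#' @return a filtered [label_volume()].
#' @export
filter_small_components <- function(labels, params = postprocess_params()) {
  stopifnot(inherits(labels, "label_volume"))
  if (params$min_component_vox <= 0L) return(labels)
  sch <- labels$scheme
  bg <- if (is.null(params$removed_to)) sch$background_id
        else as.integer(params$removed_to)
  labs <- labels$labels
  masks <- if (params$filter_scope == "per_class") {
    ids <- setdiff(sort(unique(as.vector(labs))), bg)
    lapply(ids, function(cid) labs == cid)
  } else {
    list(labs != bg)
  }
  for (m in masks) {
    comp <- label_components(m, params$connectivity)
    sz <- tabulate(comp[comp > 0L])
    drop <- which(sz < params$min_component_vox)
    if (length(drop)) labs[comp %in% drop] <- bg
  }
  label_volume(labs, sch, labels$voxel_size_mm)
}

#' Full post-processing chain
#'
#' Smooth the pseudo-probabilities, take the voxelwise argmax, then remove
#' small connected components — in that order.
#'
#' @param probs a [prob_map()].
#' @param params a [postprocess_params()].
#' @return a [label_volume()].
#' @export
postprocess_segmentation <- function(probs, params = postprocess_params()) {
  filter_small_components(argmax_labels(smooth_probabilities(probs, params),
                                        params),
                          params)
}
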