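#' Configure the voxel feature bank
#'
#' The feature stage turns the four raw modalities (plus the ceT1w - nT1w
#' subtraction channel) into a per-voxel feature stack: each input channel is
#' passed through a two-scale filter bank of six rotation-covariant filters.
#' With the defaults this yields 5 raw + 5 x (6 filters x 2 scales) = 65
#' channels.
#'
#' @param scales_vox smoothing scales in voxels, strictly increasing
#'   (default `c(1.0, 3.5)`; the grid is 1 mm isotropic so voxels = mm).
#' @param filter_types ordered subset of `gaussian_smoothing`,
#'   `laplacian_of_gaussian`, `difference_of_gaussians`,
#'   `gaussian_gradient_magnitude`, `structure_tensor_eig`, `hessian_eig`.
#'   The two eigenvalue filters emit the largest eigenvalue only (one channel
#'   per filter and scale).
#' @param include_t1_subtraction append the ceT1w - nT1w channel as a fifth
#'   raw channel (default TRUE).
#' @param dog_ratio ratio k of the difference-of-Gaussians G(s) - G(k s)
#'   (default 1.5).
#' @return an object of class `feature_config`.
#' @export
feature_config <- function(scales_vox = c(1.0, 3.5),
                           filter_types = c("gaussian_smoothing",
                                            "laplacian_of_gaussian",
                                            "difference_of_gaussians",
                                            "gaussian_gradient_magnitude",
                                            "structure_tensor_eig",
                                            "hessian_eig"),
                           include_t1_subtraction = TRUE,
                           dog_ratio = 1.5) {
  known <- c("gaussian_smoothing", "laplacian_of_gaussian",
             "difference_of_gaussians", "gaussian_gradient_magnitude",
             "structure_tensor_eig", "hessian_eig")
  stopifnot(length(scales_vox) >= 1L, all(scales_vox > 0),
            !is.unsorted(scales_vox, strictly = TRUE),
            length(filter_types) >= 1L, dog_ratio > 1)
  bad <- setdiff(filter_types, known)
  if (length(bad)) stop("unknown filter type(s): ", paste(bad, collapse = ", "))
  structure(
    list(scales_vox = as.numeric(scales_vox), filter_types = filter_types,
         include_t1_subtraction = isTRUE(include_t1_subtraction),
         dog_ratio = dog_ratio),
    class = "feature_config"
  )
}

#' Subtraction channel ceT1w - nT1w
#'
#' Voxelwise difference of the contrast-enhanced and native T1-weighted
#' channels; appended as a fifth raw channel so the classifier sees contrast
#' uptake directly.
#'
#' @param ceT1w,nT1w 3D arrays on identical grids.
#' @return 3D array `ceT1w - nT1w`.
#' @export
subtract_t1 <- function(ceT1w, nT1w) {
  if (!identical(dim(ceT1w), dim(nT1w)))
    stop("ceT1w and nT1w grids differ: ",
         paste(dim(ceT1w), collapse = "x"), " vs ",
         paste(dim(nT1w), collapse = "x"))
  ceT1w - nT1w
}

# One (filter, scale) response for a single channel.
apply_filter <- function(vol, type, sigma, dog_ratio = 1.5) {
  switch(
    type,
    gaussian_smoothing = gaussian_smooth3(vol, sigma),
    laplacian_of_gaussian =
      gaussian_hessian_comp(vol, sigma, 1, 1) +
      gaussian_hessian_comp(vol, sigma, 2, 2) +
      gaussian_hessian_comp(vol, sigma, 3, 3),
    difference_of_gaussians =
      gaussian_smooth3(vol, sigma) - gaussian_smooth3(vol, dog_ratio * sigma),
    gaussian_gradient_magnitude = {
      gx <- gaussian_gradient_axis(vol, sigma, 1)
      gy <- gaussian_gradient_axis(vol, sigma, 2)
      gz <- gaussian_gradient_axis(vol, sigma, 3)
      sqrt(gx^2 + gy^2 + gz^2)
    },
    structure_tensor_eig = {
      # gradient at the inner scale sigma/2, tensor smoothed at sigma
      si <- sigma / 2
      gx <- gaussian_gradient_axis(vol, si, 1)
      gy <- gaussian_gradient_axis(vol, si, 2)
      gz <- gaussian_gradient_axis(vol, si, 3)
      e <- sym3_largest_eig(
        gaussian_smooth3(gx * gx, sigma), gaussian_smooth3(gy * gy, sigma),
        gaussian_smooth3(gz * gz, sigma), gaussian_smooth3(gx * gy, sigma),
        gaussian_smooth3(gx * gz, sigma), gaussian_smooth3(gy * gz, sigma))
      array(e, dim(vol))
    },
    hessian_eig = {
      e <- sym3_largest_eig(
        gaussian_hessian_comp(vol, sigma, 1, 1),
        gaussian_hessian_comp(vol, sigma, 2, 2),
        gaussian_hessian_comp(vol, sigma, 3, 3),
        gaussian_hessian_comp(vol, sigma, 1, 2),
        gaussian_hessian_comp(vol, sigma, 1, 3),
        gaussian_hessian_comp(vol, sigma, 2, 3))
      array(e, dim(vol))
    },
    stop("unknown filter type: ", type)
  )
}

#' Run one channel through the filter bank
#'
#' Computes one response grid per (filter type, scale) pair, named
#' `<filter>_<scale>`.  Eigenvalue filters contribute the largest eigenvalue
#' (one grid each).
#'
#' @param channel 3D array, finite-valued.
#' @param config a [feature_config()].
#' @return named list of 3D arrays, `length(filter_types) * length(scales)`
#'   entries in filter-major order.
#' @export
filter_bank <- function(channel, config = feature_config()) {
  stopifnot(inherits(config, "feature_config"))
  if (!all(is.finite(channel))) stop("input channel contains non-finite values")
  out <- list()
  for (ft in config$filter_types) {
    for (s in config$scales_vox) {
      out[[paste0(ft, "_", format(s, trim = TRUE))]] <-
        apply_filter(channel, ft, s, config$dog_ratio)
    }
  }
  out
}

#' Assemble the full per-voxel feature stack of a study
#'
#' Channel order (versioned, stable): the 4 raw modalities (nT1w, ceT1w,
#' T2w, FLAIR), the T1 subtraction channel (if enabled), then for each raw
#' channel the filter bank responses in filter-major, scale-minor order.
#' With the default configuration this is 5 + 5 x 12 = 65 channels.
#'
#' @param study [mc_volume()] with channels nT1w, ceT1w, T2w, FLAIR.
#' @param config a [feature_config()].
#' @return [mc_volume()] with the named feature channels.
#' @export
assemble_feature_stack <- function(study, config = feature_config()) {
  stopifnot(inherits(study, "mc_volume"), inherits(config, "feature_config"))
  need <- c("nT1w", "ceT1w", "T2w", "FLAIR")
  miss <- setdiff(need, channel_names(study))
  if (length(miss)) stop("missing modality channel(s): ",
                         paste(miss, collapse = ", "))
  raw <- study$channels[need]
  if (config$include_t1_subtraction)
    raw[["T1sub"]] <- subtract_t1(raw[["ceT1w"]], raw[["nT1w"]])
  out <- raw
  for (nm in names(raw)) {
    fb <- filter_bank(raw[[nm]], config)
    names(fb) <- paste0(nm, ".", names(fb))
    out <- c(out, fb)
  }
  mc_volume(out, study$voxel_size_mm)
}

# Feature matrix (n_voxels x n_channels) for a set of 0-based voxel
# coordinates, in the stack's channel order.
features_at <- function(stack, xyz0) {
  xyz0 <- as.matrix(xyz0)
  d <- dim(stack)
  if (nrow(xyz0) == 0L)
    return(matrix(numeric(0), 0L, length(stack$channels),
                  dimnames = list(NULL, channel_names(stack))))
  lim <- matrix(d, nrow(xyz0), 3L, byrow = TRUE)
  bad <- which(rowSums(xyz0 < 0 | xyz0 >= lim) > 0)
  if (length(bad))
    stop("voxel coordinate out of bounds: (",
         paste(xyz0[bad[1], ], collapse = ","), ")")
  lin <- 1L + xyz0[, 1] + d[1] * (xyz0[, 2] + d[2] * xyz0[, 3])
  m <- vapply(stack$channels, function(ch) ch[lin], numeric(nrow(xyz0)))
  if (nrow(xyz0) == 1L) m <- matrix(m, nrow = 1L,
                                    dimnames = list(NULL, channel_names(stack)))
  m
}
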