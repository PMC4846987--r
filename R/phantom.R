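#' Specify a synthetic multi-channel brain-tumor phantom
#'
#' Defines the geometry, intensity model and noise of a simulated
#' four-modality MRI study (nT1w, ceT1w, T2w, FLAIR) with a nested tumor
#' (necrosis / non-enhancing core inside an enhancing rim inside edema) on a
#' known ground-truth label grid.  The phantom emulates co-registered,
#' 1 mm-isotropic, brain-extracted data; MR physics (Rician noise, partial
#' volume) is deliberately not modeled.
#'
#' @param grid_shape voxel counts per axis (each >= 16).
#' @param voxel_size_mm spacing in mm (default 1 mm isotropic).
#' @param scheme label scheme; [scheme_gb6()] (default) or [scheme_brats5()].
#' @param tumor_center tumor center voxel (default slightly off grid center).
#' @param tumor_radii named increasing radii (voxels) of the nested tumor
#'   regions, innermost first; names must be scheme classes.  Defaults depend
#'   on the scheme.
#' @param growth_factor per-timepoint radial scale multiplier (default 1.2).
#' @param n_timepoints number of longitudinal timepoints (default 2).
#' @param intensity_model per-class, per-channel intensity means and sds
#'   (arbitrary units); see [default_intensity_model()].
#' @param noise_sd additive Gaussian noise sd per channel (default 4).
#' @param bias_amplitude amplitude in `[0, 1)` of the multiplicative
#'   low-frequency bias field (product of per-axis half-period cosines).
#' @param seed master RNG seed.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(32L, 32L, 32L),
                         voxel_size_mm = c(1, 1, 1),
                         scheme = scheme_gb6(),
                         tumor_center = NULL,
                         tumor_radii = NULL,
                         growth_factor = 1.2,
                         n_timepoints = 2L,
                         intensity_model = NULL,
                         noise_sd = 4,
                         bias_amplitude = 0.1,
                         seed = 1L) {
  grid_shape <- as.integer(grid_shape)
  stopifnot(length(grid_shape) == 3L, all(grid_shape >= 16L),
            noise_sd >= 0, bias_amplitude >= 0, bias_amplitude < 1,
            growth_factor > 0, n_timepoints >= 1L)
  if (is.null(tumor_center)) tumor_center <- grid_shape / 2 + c(1.5, 0.5, -0.5)
  if (is.null(tumor_radii)) {
    sc <- min(grid_shape) / 32
    tumor_radii <- if ("Necrosis" %in% class_names(scheme)) {
      c(Necrosis = 2, NonEnhancing = 3.5, Enhancing = 6.5, Edema = 9) * sc
    } else {
      c(NonEnhancing = 3.5, Enhancing = 6.5, Edema = 9) * sc
    }
  }
  if (is.null(names(tumor_radii)) ||
      !all(names(tumor_radii) %in% class_names(scheme)))
    stop("tumor_radii must be named with scheme classes")
  if (any(diff(tumor_radii) <= 0))
    stop("tumor radii must be strictly increasing outward")
  if (is.null(intensity_model)) intensity_model <- default_intensity_model(scheme)
  structure(
    list(grid_shape = grid_shape, voxel_size_mm = as.numeric(voxel_size_mm),
         scheme = scheme, tumor_center = as.numeric(tumor_center),
         tumor_radii = tumor_radii, growth_factor = growth_factor,
         n_timepoints = as.integer(n_timepoints),
         intensity_model = intensity_model,
         noise_sd = rep_len(as.numeric(noise_sd), 4L),
         bias_amplitude = bias_amplitude, seed = as.integer(seed)),
    class = "phantom_spec"
  )
}

#' Default per-class intensity model
#'
#' Mean and sd of each raw channel per tissue class, in arbitrary intensity
#' units chosen so that: contrast enhancement (ceT1w > nT1w) occurs only in
#' the enhancing class; edema and tumor are bright on T2w/FLAIR; CSF is
#' bright on T2w but suppressed on FLAIR; air is zero.
#'
#' @param scheme a [label_scheme()].
#' @return tibble with columns `name`, `channel`, `mean`, `sd`.
#' @export
default_intensity_model <- function(scheme) {
  base <- list(
    Air          = c(0, 0, 0, 0),
    Rest         = c(70, 70, 50, 45),
    Normal       = c(70, 70, 50, 45),
    CSF          = c(25, 25, 90, 20),
    Edema        = c(55, 55, 75, 80),
    NonEnhancing = c(45, 45, 70, 65),
    Necrosis     = c(30, 30, 80, 55),
    Enhancing    = c(60, 85, 65, 60)
  )
  chans <- c("nT1w", "ceT1w", "T2w", "FLAIR")
  rows <- lapply(class_names(scheme), function(nm) {
    mu <- base[[nm]]
    if (is.null(mu)) stop("no default intensities for class ", nm)
    tibble::tibble(name = nm, channel = chans, mean = mu,
                   sd = if (nm == "Air") 0 else 2)
  })
  dplyr::bind_rows(rows)
}

# Squared normalized ellipsoid distance of every voxel to a center.
ellipsoid_field <- function(grid_shape, center, semi_axes) {
  x <- (seq_len(grid_shape[1]) - center[1]) / semi_axes[1]
  y <- (seq_len(grid_shape[2]) - center[2]) / semi_axes[2]
  z <- (seq_len(grid_shape[3]) - center[3]) / semi_axes[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`)
}

# Non-tumor anatomy for a spec: base class everywhere, plus (for schemes with
# an Air exterior) a brain ellipsoid of background tissue and a CSF sphere.
anatomy_labels <- function(spec) {
  gs <- spec$grid_shape
  sch <- spec$scheme
  ids <- class_ids(sch)
  names(ids) <- class_names(sch)
  if ("Air" %in% class_names(sch)) {
    labs <- array(ids[["Air"]], gs)
    brain <- ellipsoid_field(gs, gs / 2 + 0.5, 0.42 * gs) <= 1
    labs[brain] <- spec$scheme$background_id
    if ("CSF" %in% class_names(sch)) {
      csf_c <- spec$tumor_center - c(0.32, 0.28, 0) * gs
      csf <- ellipsoid_field(gs, csf_c, rep(0.09 * min(gs), 3)) <= 1
      labs[csf & brain] <- ids[["CSF"]]
    }
  } else {
    labs <- array(sch$background_id, gs)
  }
  storage.mode(labs) <- "integer"
  labs
}

#' Generate one timepoint of a phantom study
#'
#' Builds the ground-truth label grid (nested tumor regions scaled by
#' `growth_factor^timepoint`) and the four noisy raw channels.  Fully
#' deterministic given the spec's seed.
#'
#' @param spec a [phantom_spec()].
#' @param timepoint 0-based timepoint index (`< spec$n_timepoints`).
#' @return list with elements `image` ([mc_volume()], channels nT1w, ceT1w,
#'   T2w, FLAIR) and `truth` ([label_volume()]).
#' @export
generate_phantom <- function(spec, timepoint = 0L) {
  stopifnot(inherits(spec, "phantom_spec"),
            timepoint >= 0L, timepoint < spec$n_timepoints)
  gs <- spec$grid_shape
  sch <- spec$scheme
  ids <- stats::setNames(class_ids(sch), class_names(sch))
  scale <- spec$growth_factor^timepoint
  radii <- spec$tumor_radii * scale
  for (i in seq_along(radii)) {
    r <- radii[i]
    lo <- spec$tumor_center - r
    hi <- spec$tumor_center + r
    if (any(lo < 1) || any(hi > gs))
      stop("tumor region '", names(radii)[i], "' (radius ", signif(r, 4),
           " voxels at timepoint ", timepoint, ") exceeds the grid bounds")
  }
  labs <- anatomy_labels(spec)
  # paint tumor outermost-in so inner regions overwrite outer shells
  for (i in rev(seq_along(radii))) {
    m <- ellipsoid_field(gs, spec$tumor_center, rep(radii[i], 3)) <= 1
    labs[m] <- ids[[names(radii)[i]]]
  }
  truth <- label_volume(labs, sch, spec$voxel_size_mm)

  im <- spec$intensity_model
  chans <- unique(im$channel)
  mu_tab <- matrix(0, n_classes(sch), length(chans),
                   dimnames = list(class_names(sch), chans))
  sd_tab <- mu_tab
  for (r in seq_len(nrow(im))) {
    mu_tab[im$name[r], im$channel[r]] <- im$mean[r]
    sd_tab[im$name[r], im$channel[r]] <- im$sd[r]
  }
  bias <- if (spec$bias_amplitude > 0) {
    cx <- cos(pi * (seq_len(gs[1]) - 1) / (gs[1] - 1))
    cy <- cos(pi * (seq_len(gs[2]) - 1) / (gs[2] - 1))
    cz <- cos(pi * (seq_len(gs[3]) - 1) / (gs[3] - 1))
    1 + spec$bias_amplitude * outer(outer(cx, cy), cz)
  } else {
    array(1, gs)
  }
  lab_idx <- as.vector(labs) + 1L
  channels <- with_seed(derive_seed(spec$seed, "phantom", timepoint), {
    out <- list()
    for (ch in chans) {
      mu <- mu_tab[lab_idx, ch]
      cs <- sd_tab[lab_idx, ch]
      v <- mu * as.vector(bias)
      if (any(cs > 0)) v <- v + stats::rnorm(length(v), 0, cs)
      nsd <- spec$noise_sd[match(ch, chans)]
      if (nsd > 0) v <- v + stats::rnorm(length(v), 0, nsd)
      out[[ch]] <- array(v, gs)
    }
    out
  })
  list(image = mc_volume(channels, spec$voxel_size_mm), truth = truth)
}

#' Specify a simulated imperfect rater
#'
#' A rater perturbs region boundaries by a systematic signed radius
#' (`boundary_bias_vox`, dilation when positive) plus a per-class random
#' jitter, confuses classes within a one-voxel shell around boundaries
#' according to a confusion table, and emits sparse scribbles from the
#' interior (one-voxel erosion) of each region.
#'
#' @param boundary_bias_vox signed systematic dilation(+)/erosion(-) radius
#'   in voxels applied to each perturbed class boundary.
#' @param boundary_jitter_sd sd (voxels) of the per-class random radius
#'   perturbation added to the bias on every call.
#' @param confusion named list: for a true class name, a named probability
#'   vector of observed classes (applied only in the boundary shell); row
#'   sums must be <= 1, the residual keeps the correct label.
#' @param scribble_fraction fraction of each eroded region emitted as
#'   scribbles, in `(0, 1]`.
#' @param min_scribbles_per_class raters annotate every class they can see:
#'   at least this many scribbles are emitted per class (capped by the
#'   eroded-region size), even when the fraction alone would give fewer
#'   (default 20).
#' @param perturb_classes classes whose boundaries are perturbed; default:
#'   the scheme's tumor classes plus Edema (resolved at simulation time).
#' @param seed RNG seed; simulation is deterministic given the seed, so
#'   distinct (patient, timepoint, run) cells should carry derived seeds.
#' @return an object of class `rater_model`.
#' @export
rater_model <- function(boundary_bias_vox = 0,
                        boundary_jitter_sd = 0.7,
                        confusion = NULL,
                        scribble_fraction = 0.05,
                        min_scribbles_per_class = 20L,
                        perturb_classes = NULL,
                        seed = 1L) {
  stopifnot(scribble_fraction > 0, scribble_fraction <= 1,
            boundary_jitter_sd >= 0)
  if (!is.null(confusion)) {
    for (nm in names(confusion)) {
      p <- confusion[[nm]]
      if (any(p < 0) || sum(p) > 1)
        stop("confusion row for '", nm, "' must be non-negative and sum to <= 1")
    }
  }
  structure(
    list(boundary_bias_vox = boundary_bias_vox,
         boundary_jitter_sd = boundary_jitter_sd,
         confusion = confusion,
         scribble_fraction = scribble_fraction,
         min_scribbles_per_class = as.integer(min_scribbles_per_class),
         perturb_classes = perturb_classes,
         seed = as.integer(seed)),
    class = "rater_model"
  )
}

#' Simulate an imperfect rater's dense segmentation
#'
#' Applies the rater model to a ground-truth label volume: each perturbed
#' class boundary is displaced by `bias + N(0, jitter_sd)` voxels (sub-voxel
#' displacement via Gaussian level sets), perturbed regions are recomposed
#' largest-first so nested structures stay nested, and boundary-shell voxels
#' are then confused according to the model's confusion table.  Deterministic
#' given the model seed.
#'
#' @param truth a [label_volume()] ground truth.
#' @param model a [rater_model()].
#' @return a [label_volume()] with the rater's segmentation.
#' @export
simulate_rater <- function(truth, model) {
  stopifnot(inherits(truth, "label_volume"), inherits(model, "rater_model"))
  sch <- truth$scheme
  ids <- stats::setNames(class_ids(sch), class_names(sch))
  pert <- model$perturb_classes
  if (is.null(pert)) {
    pert <- class_names(sch)[ids %in% sch$tumor_class_ids]
    if ("Edema" %in% class_names(sch)) pert <- c(pert, "Edema")
  }
  bad <- setdiff(c(pert, names(model$confusion),
                   unlist(lapply(model$confusion, names))), class_names(sch))
  if (length(bad)) stop("rater model references unknown classes: ",
                        paste(bad, collapse = ", "))
  labs <- truth$labels
  with_seed(derive_seed(model$seed, "rater"), {
    masks <- list()
    sizes <- numeric(0)
    for (nm in pert) {
      m <- labs == ids[[nm]]
      delta <- model$boundary_bias_vox +
        if (model$boundary_jitter_sd > 0)
          stats::rnorm(1, 0, model$boundary_jitter_sd) else 0
      masks[[nm]] <- perturb_mask(m, delta)
      sizes[nm] <- sum(m)
    }
    if (length(masks)) {
      # clear perturbed classes to background, repaint largest (outermost) first
      labs[labs %in% ids[pert]] <- sch$background_id
      for (nm in names(sort(sizes, decreasing = TRUE))) {
        labs[masks[[nm]]] <- ids[[nm]]
      }
    }
    if (!is.null(model$confusion)) {
      shell <- boundary_shell(labs)
      for (nm in names(model$confusion)) {
        p <- model$confusion[[nm]]
        idx <- which(shell & labs == ids[[nm]])
        if (!length(idx)) next
        u <- stats::runif(length(idx))
        cum <- 0
        for (tgt in names(p)) {
          take <- u >= cum & u < cum + p[[tgt]]
          labs[idx[take]] <- ids[[tgt]]
          cum <- cum + p[[tgt]]
        }
      }
    }
    label_volume(labs, sch, truth$voxel_size_mm)
  })
}

#' Extract sparse scribbles from a dense segmentation
#'
#' Samples high-confidence sparse annotations: per class, voxels are drawn
#' without replacement only from the one-voxel morphological erosion of the
#' labeled region (scribbles never touch class boundaries); the per-class
#' count is `floor(scribble_fraction * eroded_region_size)`, floored at the
#' model's `min_scribbles_per_class` (and capped by the region size).
#'
#' @param dense a [label_volume()].
#' @param model a [rater_model()] supplying `scribble_fraction` and the seed.
#' @return a tibble with columns `x`, `y`, `z` (0-based voxel indices) and
#'   `class_id`; attribute `scheme` carries the label scheme.
#' @export
extract_scribbles <- function(dense, model) {
  stopifnot(inherits(dense, "label_volume"), inherits(model, "rater_model"))
  sch <- dense$scheme
  d <- dim(dense$labels)
  rows <- list()
  for (cid in class_ids(sch)) {
    m <- dense$labels == cid
    if (!any(m)) next
    er <- binary_erode1(m)
    idx <- which(er)
    n_take <- min(length(idx),
                  max(floor(model$scribble_fraction * length(idx)),
                      model$min_scribbles_per_class))
    if (length(idx) == 0L || n_take == 0L) {
      rlang::inform(paste0("class ", cid, " (",
                           class_names(sch)[cid + 1L],
                           "): eroded region too small, no scribbles emitted"),
                    class = "virtrater_empty_scribbles")
      next
    }
    take <- with_seed(derive_seed(model$seed, "scribbles", cid),
                      sample(idx, n_take))
    co <- arrayInd(take, d)
    rows[[length(rows) + 1L]] <-
      tibble::tibble(x = co[, 1] - 1L, y = co[, 2] - 1L, z = co[, 3] - 1L,
                     class_id = cid)
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else
    tibble::tibble(x = integer(), y = integer(), z = integer(),
                   class_id = integer())
  attr(out, "scheme") <- sch
  out
}
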