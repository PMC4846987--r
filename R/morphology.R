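# Binary 3D morphology helpers: connected-component labelling, one-voxel
# erosion, and sub-voxel boundary perturbation for the simulated raters.

# Shift/pad machinery: pad with one background layer so neighbor linear
# offsets never wrap across array edges.
pad_mask <- function(mask) {
  d <- dim(mask)
  pm <- array(FALSE, d + 2L)
  pm[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- mask
  pm
}

unpad <- function(pm, d) {
  array(pm[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)], d)
}

neighbor_offsets <- function(pd, connectivity = 26L) {
  sh <- expand.grid(di = -1:1, dj = -1:1, dk = -1:1)
  sh <- sh[!(sh$di == 0 & sh$dj == 0 & sh$dk == 0), ]
  if (connectivity == 6L)
    sh <- sh[abs(sh$di) + abs(sh$dj) + abs(sh$dk) == 1L, ]
  else if (connectivity != 26L)
    stop("connectivity must be 6 or 26")
  as.integer(sh$di + sh$dj * pd[1] + sh$dk * pd[1] * pd[2])
}

#' Label connected components of a binary 3D mask
#'
#' Flood-fill labelling under 26- (default) or 6-neighborhood connectivity.
#'
#' @param mask logical 3D array.
#' @param connectivity 26 (vertex-sharing) or 6 (face-sharing).
#' @return integer array of the same shape; 0 = background, components are
#'   numbered from 1 in scan order.
#' @export
label_components <- function(mask, connectivity = 26L) {
  d <- dim(mask)
  pm <- pad_mask(mask)
  pd <- dim(pm)
  offs <- neighbor_offsets(pd, connectivity)
  pmv <- as.logical(pm)
  lab <- integer(length(pmv))
  cur <- 0L
  for (s in which(pmv)) {
    if (lab[s] > 0L) next
    cur <- cur + 1L
    lab[s] <- cur
    frontier <- s
    while (length(frontier)) {
      nb <- unique(as.vector(outer(frontier, offs, `+`)))
      nb <- nb[pmv[nb] & lab[nb] == 0L]
      lab[nb] <- cur
      frontier <- nb
    }
  }
  unpad(array(lab, pd), d)
}

# One-voxel binary erosion under the face-sharing (6-) neighborhood: a voxel
# survives iff it and all six face neighbors are foreground.
binary_erode1 <- function(mask) {
  pm <- pad_mask(mask)
  pd <- dim(pm)
  out <- pm
  n <- length(pm)
  for (o in neighbor_offsets(pd, 6L)) {
    # clamp: out-of-range shifts only touch the padded border, which is FALSE
    idx <- pmin(pmax(seq_len(n) + o, 1L), n)
    out <- out & array(as.logical(pm)[idx], pd)
  }
  unpad(out, dim(mask))
}

# Sub-voxel dilation (delta > 0) or erosion (delta < 0) of a binary mask:
# smooth the indicator with a Gaussian of width `sigma` and threshold at
# pnorm(-delta / sigma).  For a flat boundary this displaces the 0.5 level
# set by exactly `delta` voxels; delta = 0 returns the mask unchanged.
perturb_mask <- function(mask, delta, sigma = 1.0) {
  if (delta == 0) return(mask)
  sm <- gaussian_smooth3(array(as.numeric(mask), dim(mask)), sigma)
  sm >= stats::pnorm(-delta / sigma)
}

# Boundary shell of a labelled volume: voxels with at least one 6-neighbor
# of a different label.
boundary_shell <- function(labels) {
  pm <- array(-1L, dim(labels) + 2L)
  d <- dim(labels)
  pm[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- labels
  pd <- dim(pm)
  shell <- array(FALSE, pd)
  inner <- array(FALSE, pd)
  inner[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- TRUE
  pv <- as.integer(pm)
  n <- length(pv)
  for (o in neighbor_offsets(pd, 6L)) {
    nb <- pv[pmin(pmax(seq_len(n) + o, 1L), n)]
    shell <- shell | (inner & array(nb != pv & nb >= 0L, pd))
  }
  unpad(shell, d)
}
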