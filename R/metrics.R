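#' Dice overlap coefficient
#'
#' Twice the intersection size divided by the sum of the two mask sizes.
#' Identical segmentations score 1.0; two empty masks are identical and also
#' score 1.0 (convention).
#'
#' @param a,b logical arrays on the same grid.
#' @return Dice score in `[0, 1]`.
#' @export
dice <- function(a, b) {
  if (!identical(dim(a), dim(b))) stop("mask grids differ")
  sa <- sum(a)
  sb <- sum(b)
  if (sa + sb == 0) return(1.0)
  2 * sum(a & b) / (sa + sb)
}

#' Pearson correlation with two-sided p-value
#'
#' Standard product-moment correlation; the p-value comes from the exact t
#' transform (via [stats::cor.test()]).
#'
#' @param x,y numeric series of equal length, n >= 3, non-constant.
#' @return one-row tibble with `r`, `p_value`, `n`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("zero variance in input series")
  ct <- stats::cor.test(x, y, method = "pearson")
  tibble::tibble(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' One-way random-effects intraclass correlation, ICC(1)
#'
#' McGraw & Wong case 1: `ICC(1) = (MSB - MSW) / (MSB + (k - 1) MSW)` with
#' the between- and within-subject mean squares from a one-way ANOVA of the
#' `n x k` ratings table (subjects = random rows, k ratings per subject).
#' The p-value is the upper tail of `F = MSB / MSW` on `(n - 1, n(k - 1))`
#' degrees of freedom.
#'
#' @param ratings numeric matrix or data frame, `n` subjects x `k` ratings;
#'   must be complete.
#' @return one-row tibble with `icc`, `p_value`, `f_statistic`, `df1`, `df2`.
#' @export
icc1_oneway <- function(ratings) {
  m <- as.matrix(ratings)
  if (anyNA(m)) stop("ratings table must be complete (no missing values)")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2L || k < 2L) stop("need >= 2 subjects and >= 2 ratings per subject")
  row_means <- rowMeans(m)
  grand <- mean(m)
  msb <- k * sum((row_means - grand)^2) / (n - 1)
  msw <- sum((m - row_means)^2) / (n * (k - 1))
  icc <- (msb - msw) / (msb + (k - 1) * msw)
  f <- msb / msw
  tibble::tibble(icc = icc,
                 p_value = stats::pf(f, n - 1, n * (k - 1), lower.tail = FALSE),
                 f_statistic = f, df1 = n - 1, df2 = n * (k - 1))
}

#' Combine independent p-values with Fisher's method
#'
#' `X^2 = -2 sum(log p_i)` referred to the upper tail of a chi-square
#' distribution with `2k` degrees of freedom.
#'
#' @param p_values numeric vector of p-values in `(0, 1]`.
#' @return one-row tibble with `statistic`, `df`, `p_value`.
#' @export
fisher_combine <- function(p_values) {
  stopifnot(length(p_values) >= 1L)
  if (any(p_values <= 0) || any(p_values > 1))
    stop("p-values must lie in (0, 1]; clip zeros before combining")
  x2 <- -2 * sum(log(p_values))
  df <- 2L * length(p_values)
  tibble::tibble(statistic = x2, df = df,
                 p_value = stats::pchisq(x2, df, lower.tail = FALSE))
}

#' Per-class volumes and gross tumor volume
#'
#' Voxel counts per class times the voxel volume; the GTV merges the scheme's
#' tumor-related classes.
#'
#' @param labels a [label_volume()].
#' @return tibble with one row per scheme class (`class_id`, `name`,
#'   `n_voxels`, `volume_mm3`, `is_tumor`); attribute `gtv_mm3` carries the
#'   merged GTV, also available via [gtv_volume()].
#' @export
class_volumes <- function(labels) {
  stopifnot(inherits(labels, "label_volume"))
  sch <- labels$scheme
  vx <- prod(labels$voxel_size_mm)
  counts <- tabulate(as.vector(labels$labels) + 1L, nbins = n_classes(sch))
  out <- tibble::tibble(
    class_id = class_ids(sch),
    name = class_names(sch),
    n_voxels = counts,
    volume_mm3 = counts * vx,
    is_tumor = class_ids(sch) %in% sch$tumor_class_ids
  )
  attr(out, "gtv_mm3") <- sum(out$volume_mm3[out$is_tumor])
  out
}

#' @rdname class_volumes
#' @export
gtv_volume <- function(labels) {
  vols <- class_volumes(labels)
  sum(vols$volume_mm3[vols$is_tumor])
}

#' Longitudinal relative change versus baseline (dGTV)
#'
#' Percent change of each timepoint's GTV relative to the first (baseline)
#' value: `100 * (gtv_t - gtv_0) / gtv_0`.
#'
#' @param gtv_mm3 numeric vector of GTVs ordered in time; the first element
#'   is the baseline and must be positive.
#' @return numeric vector of percent changes (baseline = 0).
#' @export
relative_change_series <- function(gtv_mm3) {
  stopifnot(length(gtv_mm3) >= 1L)
  if (gtv_mm3[1] <= 0) stop("baseline GTV must be positive")
  100 * (gtv_mm3 - gtv_mm3[1]) / gtv_mm3[1]
}

#' Volumetric response thresholds
#'
#' RANO-style cutoffs on relative volume change: a +25% increase defines
#' progression and a -50% decrease a partial response (both inclusive).  The
#' alternative volumetric cutoffs (+40% / -65%) proposed for volume-based
#' assessment are carried alongside.
#'
#' @param progression_increase_pct,response_decrease_pct primary cutoffs
#'   (defaults 25 and 50).
#' @param alt_progression_pct,alt_response_pct alternative volumetric cutoffs
#'   (defaults 40 and 65).
#' @return an object of class `response_thresholds`.
#' @export
response_thresholds <- function(progression_increase_pct = 25,
                                response_decrease_pct = 50,
                                alt_progression_pct = 40,
                                alt_response_pct = 65) {
  vals <- c(progression_increase_pct, response_decrease_pct,
            alt_progression_pct, alt_response_pct)
  stopifnot(all(vals > 0), all(vals <= 100))
  structure(
    list(progression_increase_pct = progression_increase_pct,
         response_decrease_pct = response_decrease_pct,
         alt_progression_pct = alt_progression_pct,
         alt_response_pct = alt_response_pct),
    class = "response_thresholds"
  )
}

#' Classify a relative volume change
#'
#' `change >= +progression cutoff` is progression, `change <= -response
#' cutoff` is partial response, anything between is stable; boundary values
#' are inclusive.
#'
#' @param change_pct numeric vector of percent changes versus baseline.
#' @param thresholds a [response_thresholds()].
#' @param use_alt use the alternative volumetric cutoffs (40/65) instead of
#'   the primary ones (25/50).
#' @return character vector in `{"progression", "stable", "partial_response"}`.
#' @export
rano_classify <- function(change_pct, thresholds = response_thresholds(),
                          use_alt = FALSE) {
  up <- if (use_alt) thresholds$alt_progression_pct
        else thresholds$progression_increase_pct
  dn <- if (use_alt) thresholds$alt_response_pct
        else thresholds$response_decrease_pct
  dplyr::case_when(
    change_pct >= up ~ "progression",
    change_pct <= -dn ~ "partial_response",
    .default = "stable"
  )
}

#' Bidimensional (RANO-style) measurement of a lesion
#'
#' On every axial slice (third array axis) the largest in-plane connected
#' component is measured: `d1` is the longest distance between voxel centers
#' (plus one voxel extent) and `d2` the longest such distance in a direction
#' perpendicular to `d1` within +-5 degrees.  The slice maximizing
#' `d1 * d2` is reported.  Diameter endpoints are searched over all voxel
#' centers of the component (reduced to convex-hull vertices for components
#' beyond 600 in-plane voxels; `d1` is exact either way).
#'
#' @param mask logical 3D array (typically the contrast-enhancing class).
#' @param voxel_size_mm spacing in mm.
#' @param angle_tol_deg perpendicularity tolerance (default 5 degrees).
#' @return one-row tibble with `product_mm2`, `d1_mm`, `d2_mm`,
#'   `slice_index` (0-based) and `empty` flag.
#' @export
rano_product_2d <- function(mask, voxel_size_mm = c(1, 1, 1),
                            angle_tol_deg = 5) {
  stopifnot(length(dim(mask)) == 3L)
  if (!any(mask)) {
    return(tibble::tibble(product_mm2 = 0, d1_mm = 0, d2_mm = 0,
                          slice_index = NA_integer_, empty = TRUE))
  }
  sx <- voxel_size_mm[1]
  sy <- voxel_size_mm[2]
  vox <- mean(c(sx, sy))
  sin_tol <- sin(angle_tol_deg * pi / 180)
  best <- list(product = -1, d1 = 0, d2 = 0, slice = NA_integer_)
  for (z in seq_len(dim(mask)[3])) {
    sl <- mask[, , z]
    if (!any(sl)) next
    comp <- label_components(array(sl, c(dim(sl), 1L)), 26L)[, , 1]
    largest <- which.max(tabulate(comp[comp > 0L]))
    pts <- which(comp == largest, arr.ind = TRUE)
    xy <- cbind(pts[, 1] * sx, pts[, 2] * sy)
    if (nrow(xy) == 1L) {
      d1 <- vox; d2 <- vox
    } else {
      # d1 endpoints always lie on the convex hull; the perpendicular-within-
      # tolerance search for d2 may not, so keep all points for moderate
      # components and fall back to hull vertices only for very large ones
      h <- if (nrow(xy) > 600L) unique(xy[grDevices::chull(xy), , drop = FALSE])
           else unique(xy)
      if (nrow(h) < 2L) h <- unique(xy)
      pr <- utils::combn(nrow(h), 2)
      dx <- h[pr[2, ], 1] - h[pr[1, ], 1]
      dy <- h[pr[2, ], 2] - h[pr[1, ], 2]
      len <- sqrt(dx^2 + dy^2)
      i1 <- which.max(len)
      d1 <- len[i1] + vox
      u <- c(dx[i1], dy[i1]) / len[i1]
      cosang <- abs(dx * u[1] + dy * u[2]) / pmax(len, 1e-12)
      perp <- cosang <= sin_tol & len > 0
      d2 <- if (any(perp)) max(len[perp]) + vox else vox
    }
    if (d1 * d2 > best$product) {
      best <- list(product = d1 * d2, d1 = d1, d2 = d2, slice = z - 1L)
    }
  }
  tibble::tibble(product_mm2 = best$product,
                 d1_mm = max(best$d1, best$d2),
                 d2_mm = min(best$d1, best$d2),
                 slice_index = best$slice, empty = FALSE)
}
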