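#' Invasion indices A and B
#'
#' Index A is the percentage of the cell-covered area occupied by the
#' edge zone (non-aggregated invading projections); index B additionally
#' includes the loosely aggregated intermediate zone:
#' \deqn{A = 100 \cdot A_{edge} / A_{all}, \qquad
#'       B = 100 \cdot (A_{edge} + A_{intermediate}) / A_{all}
#'         = 100 \cdot (A_{all} - A_{core}) / A_{all}.}
#' Both lie in \[0, 100\] with `A <= B`; unlike cumulative parameters such
#' as total area, they report the invasion state at the time of
#' measurement without being confounded by proliferation.
#'
#' @param s a [segment()] result.
#' @return Named list with `index_A` and `index_B`, in percent.
#' @export
invasion_indices <- function(s) {
  stopifnot(inherits(s, "segmentation_result"))
  if (s$area_all <= 0)
    abort_validation("cell-covered area is zero; indices are undefined")
  list(index_A = 100 * s$area_edge / s$area_all,
       index_B = 100 * (s$area_edge + s$area_intermediate_region) / s$area_all)
}

#' Spheroid volume from projected area
#'
#' Assumes a spherical spheroid: the equivalent radius is
#' `r = sqrt(area / pi)` and the volume `(4/3) pi r^3`. With a pixel
#' calibration the result is in cubic micrometers, otherwise cubic
#' pixels.
#'
#' @param area projected area (pixels squared), strictly positive.
#' @param pixel_size optional micrometers per pixel.
#' @return Volume in pixel^3, or um^3 when calibrated.
#' @export
volume_from_area <- function(area, pixel_size = NULL) {
  check_scalar_number(area, "area")
  if (area <= 0)
    abort_validation("`area` must be strictly positive")
  if (!is.null(pixel_size)) area <- area * pixel_size^2
  r <- sqrt(area / pi)
  (4 / 3) * pi * r^3
}

#' Ratio of a metric to its reference-frame value
#'
#' Relative area and relative perimeter are conventional time-course
#' invasion parameters: the value at time t divided by the value at the
#' reference frame (day 0 or an untreated control).
#'
#' @param current value at the current frame.
#' @param reference strictly positive reference value.
#' @return `current / reference`.
#' @export
relative_metric <- function(current, reference) {
  check_scalar_number(current, "current")
  check_scalar_number(reference, "reference")
  if (reference <= 0)
    abort_validation("`reference` must be strictly positive")
  current / reference
}

#' Maximum invasion length
#'
#' The distance from the edge of the initial spheroid to the outermost
#' protruding cell: the largest Euclidean distance from any cell-covered
#' pixel at time t to the reference frame's centroid, minus the reference
#' equivalent radius `sqrt(area_ref / pi)` (clamped at 0). Measuring
#' radially from the reference centroid makes the definition
#' rotation-invariant for irregular spheroids.
#'
#' @param s_t [segment()] result at time t.
#' @param s_ref [segment()] result of the reference (initial) frame.
#' @return Length in pixels (multiply by the pixel size for micrometers).
#' @export
max_invasion_length <- function(s_t, s_ref) {
  stopifnot(inherits(s_t, "segmentation_result"),
            inherits(s_ref, "segmentation_result"))
  if (!any(s_t$mask_all) || !any(s_ref$mask_all))
    abort_validation("masks must be nonempty")
  idx <- which(s_t$mask_all, arr.ind = TRUE)
  d <- sqrt((idx[, 1L] - s_ref$centroid[1L])^2 +
            (idx[, 2L] - s_ref$centroid[2L])^2)
  r_ref <- sqrt(s_ref$area_all / pi)
  max(0, max(d) - r_ref)
}

#' Skeletonize a binary mask
#'
#' Topology-preserving 2-D thinning (Zhang–Suen) to a 1-pixel-wide
#' skeleton.
#'
#' @param mask logical matrix.
#' @return Logical skeleton matrix.
#' @export
skeletonize <- function(mask) {
  check_mask(mask)
  thin_mask_cpp(mask)
}

#' Count skeleton end-point pixels
#'
#' Thins the mask to its skeleton and counts skeleton pixels with exactly
#' one skeleton neighbor in their 8-neighborhood. Each invasive sprout
#' contributes an end point, so the count proxies the number of sprouts.
#' Thinning artifacts inside large solid blobs can add spurious end
#' points, so the count is best read comparatively along a time course.
#'
#' @param mask nonempty logical matrix.
#' @return Nonnegative integer count.
#' @export
count_endpoint_voxels <- function(mask) {
  check_mask(mask)
  if (!any(mask))
    abort_validation("cannot count end points of an empty mask")
  sk <- thin_mask_cpp(mask)
  nr <- nrow(sk); nc <- ncol(sk)
  pad <- matrix(FALSE, nr + 2L, nc + 2L)
  pad[2:(nr + 1L), 2:(nc + 1L)] <- sk
  nb <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    nb <- nb + pad[(2:(nr + 1L)) + dr, (2:(nc + 1L)) + dc]
  }
  sum(sk & nb == 1L)
}

#' Count detached cells
#'
#' Detached cells are 8-connected foreground components separate from the
#' main spheroid body: the single largest component is excluded, and the
#' remaining components with area at least `min_size` are counted.
#'
#' @param mask nonempty logical matrix.
#' @param min_size minimum component area in pixels squared (default 20).
#' @return Nonnegative integer count.
#' @export
count_detached_cells <- function(mask, min_size = 20) {
  check_mask(mask)
  if (!any(mask))
    abort_validation("cannot count detached cells in an empty mask")
  check_scalar_number(min_size, "min_size")
  lab <- label_components_cpp(mask)
  sizes <- tabulate(lab[lab > 0L])
  body <- which.max(sizes)
  sum(sizes[-body] >= min_size)
}

#' Roundness and equivalent diameter of a mask
#'
#' Roundness follows the moments-based convention
#' `4 * area / (pi * L^2)`, where `L` is the major-axis length of the
#' best-fit ellipse from the mask's second central moments
#' (`L = 4 * sqrt(lambda_max)` with `lambda_max` the largest eigenvalue of
#' the pixel-coordinate covariance matrix). A disk scores 1; elongated
#' shapes score lower. The equivalent diameter is that of the circle with
#' the same area, `2 * sqrt(area / pi)`.
#'
#' @param mask nonempty logical matrix.
#' @return Named list with `roundness` (clamped to (0, 1\]) and
#'   `equivalent_diameter` in pixels.
#' @export
shape_descriptors <- function(mask) {
  check_mask(mask)
  if (!any(mask))
    abort_validation("cannot compute shape descriptors of an empty mask")
  idx <- which(mask, arr.ind = TRUE)
  area <- nrow(idx)
  eq_diam <- 2 * sqrt(area / pi)
  if (area == 1L)
    return(list(roundness = 1, equivalent_diameter = eq_diam))
  cv <- stats::cov(idx) * (area - 1) / area  # population covariance
  lambda_max <- max(eigen(cv, symmetric = TRUE, only.values = TRUE)$values)
  if (lambda_max <= 0)
    return(list(roundness = 1, equivalent_diameter = eq_diam))
  L <- 4 * sqrt(lambda_max)
  list(roundness = min(1, 4 * area / (pi * L^2)),
       equivalent_diameter = eq_diam)
}
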